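#' Define a rhythm frequency band
#'
#' Bands are half-open intervals `[low, high)` in Hz.
#'
#' @param name Band name.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return A list of class `rhythm_band`.
#' @export
rhythm_band <- function(name, low, high) {
  if (!(low > 0 && high > low)) stop("require 0 < low < high")
  structure(list(name = name, low = low, high = high), class = "rhythm_band")
}

#' Default EEG rhythm bands
#'
#' Theta 4-8 Hz, alpha 8-14 Hz and beta 14-34 Hz: the three bands whose
#' power shifts mark the transition from alertness into NREM stage-1
#' drowsiness (theta and alpha rise, beta falls, most clearly at the
#' occipital sites O1/O2).
#'
#' @return Named list of [rhythm_band()] objects.
#' @export
default_bands <- function() {
  list(theta = rhythm_band("theta", 4, 8),
       alpha = rhythm_band("alpha", 8, 14),
       beta  = rhythm_band("beta", 14, 34))
}

#' Construct a vigilance-state profile for the simulator
#'
#' A profile fixes, for one vigilance state, the RMS amplitude of each
#' rhythm per channel group, optional rhythm bursting, artifact rates and
#' the 1/f background noise.
#'
#' @param state `"alert"` or `"drowsy"`.
#' @param band_amplitudes List with elements `occipital` and `frontal`, each
#'   a named numeric vector of RMS amplitudes in microvolts for `theta`,
#'   `alpha` and `beta`.
#' @param burst Optional list `(band, duration_s, rate_per_min,
#'   amplitude_mult)` describing rhythm bursting (e.g. drowsy alpha bursts).
#' @param artifacts List with `blink_rate` (per minute), `blink_amp` (uV,
#'   pre-frontal channels only), `emg_rate` (per minute) and `emg_amp` (uV,
#'   all channels).
#' @param noise_exponent Spectral slope of the 1/f background, in `[0, 2]`.
#' @param noise_rms RMS amplitude of the background in microvolts.
#' @param mod_depth Depth of the slow (0.05-0.5 Hz) amplitude modulation
#'   applied to every rhythm, emulating the natural waxing and waning of
#'   EEG oscillations; 0 disables it.
#' @return A list of class `state_profile`.
#' @export
state_profile <- function(state,
                          band_amplitudes,
                          burst = NULL,
                          artifacts = list(blink_rate = 12, blink_amp = 50,
                                           emg_rate = 6, emg_amp = 8),
                          noise_exponent = 1,
                          noise_rms = 4,
                          mod_depth = 0.4) {
  state <- match.arg(state, c("alert", "drowsy"))
  for (grp in c("occipital", "frontal")) {
    a <- band_amplitudes[[grp]]
    if (is.null(a) || any(a < 0) || !all(c("theta", "alpha", "beta") %in% names(a)))
      stop("band_amplitudes$", grp,
           " must be a non-negative vector naming theta, alpha, beta")
  }
  if (!is.null(burst)) {
    if (burst$duration_s <= 0) stop("burst duration must be positive")
    if (burst$rate_per_min < 0) stop("burst rate must be non-negative")
    if (burst$amplitude_mult < 1) stop("burst amplitude multiplier must be >= 1")
  }
  if (any(unlist(artifacts) < 0)) stop("artifact rates/amplitudes must be >= 0")
  if (noise_exponent < 0 || noise_exponent > 2)
    stop("noise_exponent must lie in [0, 2]")
  if (noise_rms < 0) stop("noise_rms must be >= 0")
  structure(list(state = state, band_amplitudes = band_amplitudes,
                 burst = burst, artifacts = artifacts,
                 noise_exponent = noise_exponent, noise_rms = noise_rms,
                 mod_depth = mod_depth),
            class = "state_profile")
}

#' Default alert and drowsy simulator profiles
#'
#' The drowsy profile raises occipital theta and alpha power and lowers
#' occipital beta power relative to the alert profile by configurable
#' decibel ratios, and adds alpha bursting. Frontal amplitudes and artifact
#' spectra are shared between the two states so that the discriminative
#' signal lives where it does physiologically: in the occipital band powers.
#'
#' The drowsy sustained alpha amplitude is adjusted downward so that the
#' configured dB ratio describes the *mean* drowsy/alert alpha power
#' including the burst contribution.
#'
#' @param theta_db,alpha_db,beta_db Drowsy-minus-alert power contrast in dB
#'   at the occipital channels (positive = more power when drowsy).
#' @return List with elements `alert` and `drowsy`, each a [state_profile()].
#' @export
#' @examples
#' p <- default_profiles()
#' p$drowsy$band_amplitudes$occipital["theta"] >
#'   p$alert$band_amplitudes$occipital["theta"]
default_profiles <- function(theta_db = 6, alpha_db = 6, beta_db = -3) {
  alert_occ <- c(theta = 3, alpha = 6, beta = 4)
  frontal <- c(theta = 2.5, alpha = 3, beta = 3.5)
  amp_fac <- function(db) 10^(db / 20)
  burst <- list(band = "alpha", duration_s = 1.5, rate_per_min = 6,
                amplitude_mult = 2)
  # expected fraction of drowsy time spent inside a burst
  duty <- burst$rate_per_min * burst$duration_s / 60
  # mean drowsy alpha power = base^2 * (1 + duty * (mult^2 - 1)); solve base
  burst_fac <- sqrt(1 + duty * (burst$amplitude_mult^2 - 1))
  drowsy_occ <- c(theta = alert_occ[["theta"]] * amp_fac(theta_db),
                  alpha = alert_occ[["alpha"]] * amp_fac(alpha_db) / burst_fac,
                  beta  = alert_occ[["beta"]] * amp_fac(beta_db))
  list(
    alert = state_profile("alert",
      band_amplitudes = list(occipital = alert_occ, frontal = frontal)),
    drowsy = state_profile("drowsy",
      band_amplitudes = list(occipital = drowsy_occ, frontal = frontal),
      burst = burst)
  )
}

#' Construct a vigilance-state schedule
#'
#' @param states Character vector of `"alert"` / `"drowsy"` segment states.
#' @param durations_s Positive integer segment durations in seconds
#'   (labels are per second).
#' @return A data.frame of class `state_schedule` with columns `state`,
#'   `duration_s`.
#' @export
#' @examples
#' state_schedule(c("alert", "drowsy"), c(60, 60))
state_schedule <- function(states, durations_s) {
  if (length(states) == 0) stop("schedule must contain at least one segment")
  if (length(states) != length(durations_s))
    stop("states and durations_s must have equal length")
  states <- vapply(states, match.arg, "", choices = c("alert", "drowsy"))
  if (any(durations_s < 1) || any(durations_s != round(durations_s)))
    stop("durations must be positive integer seconds")
  structure(data.frame(state = unname(states),
                       duration_s = as.integer(durations_s)),
            class = c("state_schedule", "data.frame"))
}

#' Alternating alert/drowsy study schedule
#'
#' Interleaves `blocks` alert and `blocks` drowsy segments of
#' `seconds_per_state / blocks` seconds each, so that contiguous
#' cross-validation blocks stay class-balanced.
#'
#' @param seconds_per_state Total seconds per state.
#' @param blocks Number of segments per state.
#' @return A [state_schedule()].
#' @export
alternating_schedule <- function(seconds_per_state = 300, blocks = 3) {
  seg <- seconds_per_state / blocks
  if (seg != round(seg)) stop("seconds_per_state must be divisible by blocks")
  state_schedule(rep(c("alert", "drowsy"), blocks), rep(seg, 2 * blocks))
}

#' Synthesize a band-limited EEG rhythm
#'
#' Sum of `n_components` sinusoids with frequencies drawn uniformly in
#' `[band$low, band$high)` and independent random phases, scaled to the
#' requested RMS amplitude. An optional slow amplitude modulation (envelope
#' normalized to unit mean square, so the target RMS is preserved) emulates
#' the waxing and waning of real EEG rhythms.
#'
#' @param band A [rhythm_band()].
#' @param rms_amplitude Target RMS amplitude in microvolts.
#' @param duration_s Duration in seconds (> 0).
#' @param fs Sampling rate in Hz; must exceed `2 * band$high`.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param n_components Number of sinusoids summed.
#' @param mod_depth Amplitude-modulation depth (0 disables).
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
generate_rhythm <- function(band, rms_amplitude, duration_s, fs,
                            seed = NULL, n_components = 48, mod_depth = 0) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs <= 2 * band$high)
    stop("fs violates the Nyquist criterion for band ", band$name)
  if (rms_amplitude < 0) stop("rms_amplitude must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- round(duration_s * fs)
  if (rms_amplitude == 0) return(numeric(n))
  freqs <- stats::runif(n_components, band$low, band$high)
  phases <- stats::runif(n_components, 0, 2 * pi)
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (k in seq_len(n_components))
    x <- x + sin(2 * pi * freqs[k] * tt + phases[k])
  x <- x * rms_amplitude / sqrt(mean(x^2))
  if (mod_depth > 0) {
    ef <- stats::runif(4, 0.05, 0.5)
    ep <- stats::runif(4, 0, 2 * pi)
    e <- numeric(n)
    for (k in 1:4) e <- e + sin(2 * pi * ef[k] * tt + ep[k])
    env <- pmax(1 + mod_depth * e / sqrt(mean(e^2)), 0.05)
    x <- x * env
    # the carrier and envelope are correlated in any finite sample, so
    # rescale the product itself to keep the RMS contract exact
    x <- x * rms_amplitude / sqrt(mean(x^2))
  }
  x
}

#' Synthesize 1/f background noise
#'
#' White Gaussian noise is shaped in the frequency domain so its power
#' spectrum falls as `f^-exponent` (flattened below 0.5 Hz to avoid
#' unbounded drift), then scaled to the requested RMS.
#'
#' @param noise_rms Target RMS in microvolts.
#' @param exponent Spectral slope in `[0, 2]`; 0 gives white noise.
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed.
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
generate_background <- function(noise_rms, exponent, duration_s, fs,
                                seed = NULL) {
  if (exponent < 0 || exponent > 2) stop("exponent must lie in [0, 2]")
  if (fs <= 0) stop("fs must be positive")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (noise_rms < 0) stop("noise_rms must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- round(duration_s * fs)
  if (noise_rms == 0) return(numeric(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  # two-sided frequency magnitudes for FFT bin ordering
  f <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * fs / n
  shape <- pmax(f, 0.5)^(-exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x * noise_rms / sqrt(mean(x^2))
}

# raised-cosine (Hann) gate normalized to unit mean square, so gating a
# rhythm preserves its mean power over the gate
burst_gate <- function(n) {
  g <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  g / sqrt(mean(g^2))
}

# biphasic blink pulse: one full sine period under a Hann envelope,
# spectral content ~ 1/duration (well below 5 Hz for 0.3-0.5 s blinks)
blink_pulse <- function(n, amp) {
  tt <- (seq_len(n) - 1) / (n - 1)
  amp * sin(2 * pi * tt) * (0.5 - 0.5 * cos(2 * pi * tt))
}

# add `pulse` to `sig` starting at sample `start`, truncated at the end
add_pulse <- function(sig, pulse, start) {
  stop_at <- min(start + length(pulse) - 1, length(sig))
  if (start > length(sig)) return(sig)
  k <- stop_at - start + 1
  sig[start:stop_at] <- sig[start:stop_at] + pulse[seq_len(k)]
  sig
}

#' Generate a labelled synthetic EEG recording
#'
#' Builds a multi-channel recording from a vigilance-state schedule. Each
#' segment is a sum of theta/alpha/beta rhythms at the profile's amplitudes
#' (occipital vs. frontal channel groups), optional rhythm bursts, blink
#' artifacts (pre-frontal channels only, < 5 Hz), EMG artifacts (30-100 Hz
#' bursts, all channels), and 1/f background noise. Labels are per second:
#' +1 alert, -1 drowsy.
#'
#' All randomness derives from `seed` through per-channel sub-seeds keyed to
#' the channel's position in the full montage, so the same seed reproduces
#' the same recording bit for bit, and a channel's signal does not depend on
#' which other channels are requested.
#'
#' @param schedule A [state_schedule()] (or data.frame with columns `state`,
#'   `duration_s`).
#' @param profiles List with elements `alert` and `drowsy`
#'   ([state_profile()]s); default [default_profiles()].
#' @param channels Channel labels, a subset of [EEG_MONTAGE].
#' @param fs Sampling rate in Hz (default 512).
#' @param seed Integer seed.
#' @param bands Rhythm bands synthesized, default [default_bands()].
#' @return List with elements `recording` (an [eeg_recording()]) and
#'   `labels` (per-second vector, +1 alert / -1 drowsy).
#' @export
#' @examples
#' sim <- generate_recording(state_schedule(c("alert", "drowsy"), c(5, 5)),
#'                           channels = "O1", seed = 1)
#' table(sim$labels)
generate_recording <- function(schedule, profiles = default_profiles(),
                               channels = EEG_MONTAGE, fs = 512, seed = 1,
                               bands = default_bands()) {
  if (!is.data.frame(schedule) || nrow(schedule) == 0)
    stop("empty schedule")
  unknown <- setdiff(channels, EEG_MONTAGE)
  if (length(unknown) > 0)
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  total_s <- sum(schedule$duration_s)
  labels <- rep(ifelse(schedule$state == "alert", 1L, -1L),
                times = schedule$duration_s)
  n <- total_s * fs
  out <- matrix(0, nrow = n, ncol = length(channels),
                dimnames = list(NULL, channels))
  seg_start_s <- cumsum(c(0, schedule$duration_s[-nrow(schedule)]))
  for (ch in channels) {
    ch_idx <- match(ch, EEG_MONTAGE)
    set.seed((as.integer(seed) %% 16383L) * 131071L + ch_idx * 8191L)
    grp <- if (ch %in% OCCIPITAL_CHANNELS) "occipital" else "frontal"
    sig <- numeric(n)
    for (s in seq_len(nrow(schedule))) {
      p <- profiles[[schedule$state[s]]]
      dur <- schedule$duration_s[s]
      i0 <- seg_start_s[s] * fs
      idx <- (i0 + 1):(i0 + dur * fs)
      seg <- numeric(dur * fs)
      for (b in names(bands))
        seg <- seg + generate_rhythm(bands[[b]], p$band_amplitudes[[grp]][[b]],
                                     dur, fs, mod_depth = p$mod_depth)
      if (!is.null(p$burst)) {
        bb <- p$burst
        base_amp <- p$band_amplitudes[[grp]][[bb$band]]
        extra <- base_amp * sqrt(bb$amplitude_mult^2 - 1)
        n_bursts <- stats::rpois(1, bb$rate_per_min * dur / 60)
        for (k in seq_len(n_bursts)) {
          bn <- round(bb$duration_s * fs)
          t0 <- 1 + floor(stats::runif(1, 0, max(1, dur * fs - bn)))
          pulse <- generate_rhythm(bands[[bb$band]], extra, bb$duration_s,
                                   fs) * burst_gate(bn)
          seg <- add_pulse(seg, pulse, t0)
        }
      }
      art <- p$artifacts
      n_emg <- stats::rpois(1, art$emg_rate * dur / 60)
      emg_band <- rhythm_band("emg", 30, 100)
      for (k in seq_len(n_emg)) {
        edur <- stats::runif(1, 0.2, 1)
        en <- round(edur * fs)
        t0 <- 1 + floor(stats::runif(1, 0, max(1, dur * fs - en)))
        pulse <- generate_rhythm(emg_band, art$emg_amp, edur, fs) *
          burst_gate(en)
        seg <- add_pulse(seg, pulse, t0)
      }
      if (ch %in% PREFRONTAL_CHANNELS) {
        n_blinks <- stats::rpois(1, art$blink_rate * dur / 60)
        for (k in seq_len(n_blinks)) {
          bdur <- stats::runif(1, 0.3, 0.5)
          bn <- round(bdur * fs)
          t0 <- 1 + floor(stats::runif(1, 0, max(1, dur * fs - bn)))
          seg <- add_pulse(seg, blink_pulse(bn, art$blink_amp), t0)
        }
      }
      seg <- seg + generate_background(p$noise_rms, p$noise_exponent, dur, fs)
      sig[idx] <- seg
    }
    out[, ch] <- sig
  }
  list(recording = eeg_recording(out, fs = fs,
                                 meta = list(source = "synthetic", seed = seed)),
       labels = labels)
}
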