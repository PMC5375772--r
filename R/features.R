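PSD_LOG_FLOOR <- 1e-12

hanning_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' One-second power spectral density via Hanning-windowed FFT
#'
#' Computes the one-sided periodogram of a single one-second segment
#' (exactly `fs` samples), Hanning-windowed and corrected for the window's
#' mean-square power so that the one-sided linear powers sum to the
#' segment's variance (Parseval). Frequency resolution is `fs / N` = 1 Hz
#' for one-second epochs. Powers are also reported on a log10 scale with a
#' floor of 1e-12 applied per bin before taking the log.
#'
#' @param segment Numeric vector of exactly `fs` samples.
#' @param fs Sampling rate in Hz.
#' @param epoch_index Optional second index carried along.
#' @return Object of class `epoch_psd` with `freqs` (0..fs/2), `psd`
#'   (linear one-sided power per bin) and `log_psd` (log10, floored).
#' @export
#' @examples
#' psd <- epoch_psd(sin(2 * pi * 10 * (0:511) / 512), fs = 512)
#' psd$freqs[which.max(psd$psd)] # 10 Hz
epoch_psd <- function(segment, fs, epoch_index = NA_integer_) {
  n <- length(segment)
  if (n != fs)
    stop("segment must contain exactly fs samples (one second)")
  w <- hanning_window(n)
  X <- stats::fft(segment * w)
  nb <- floor(n / 2) + 1
  p2 <- Mod(X[seq_len(nb)])^2 / (n * sum(w^2))
  scale <- rep(2, nb)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nb] <- 1
  psd <- p2 * scale
  structure(list(epoch_index = epoch_index,
                 freqs = (seq_len(nb) - 1) * fs / n,
                 psd = psd,
                 log_psd = log10(pmax(psd, PSD_LOG_FLOOR))),
            class = "epoch_psd")
}

#' Band power of an epoch spectrum
#'
#' Sums the linear power of the bins whose center frequency `f` satisfies
#' `band$low <= f < band$high` (half-open, so the shared 8 Hz and 14 Hz
#' edges are counted once), then returns log10 of the sum with the same
#' 1e-12 floor used by [epoch_psd()].
#'
#' @param psd An [epoch_psd()].
#' @param band A [rhythm_band()].
#' @return Band power on the log10 scale.
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "epoch_psd"))
  if (band$low < 0 || band$high > max(psd$freqs) + 1e-9)
    stop("band ", band$name, " lies outside the spectrum")
  idx <- psd$freqs >= band$low & psd$freqs < band$high
  log10(max(sum(psd$psd[idx]), PSD_LOG_FLOOR))
}

band_power_vector <- function(psd, bands) {
  vapply(bands, function(b) band_power(psd, b), numeric(1))
}

#' Time-window-averaged feature vector at one second
#'
#' The feature at second `t` is the arithmetic mean of the per-second
#' band-power vectors (log scale) over seconds `t - r` to `t` inclusive
#' (r + 1 epochs in total); r = 0 returns the single epoch's vector.
#'
#' @param psd_series List of [epoch_psd()] objects, one per second, in
#'   temporal order (element `i` is second `i`).
#' @param t Second index (1-based into `psd_series`).
#' @param r Averaging window in seconds, integer >= 0.
#' @param bands Named list of [rhythm_band()]s.
#' @return Named numeric feature vector (one entry per band).
#' @export
feature_at_time <- function(psd_series, t, r, bands = default_bands()) {
  if (r < 0 || r != round(r)) stop("r must be a non-negative integer")
  if (t - r < 1 || t > length(psd_series))
    stop("insufficient history: need epochs ", t - r, "..", t)
  mats <- vapply(psd_series[(t - r):t], band_power_vector, numeric(length(bands)),
                 bands = bands)
  if (is.null(dim(mats))) mats <- matrix(mats, nrow = length(bands))
  stats::setNames(rowMeans(mats), names(bands))
}

#' Extract a labelled band-power feature matrix from a recording
#'
#' Splits one channel of a (typically denoised) recording into
#' non-overlapping one-second epochs aligned to integer seconds (a trailing
#' partial second is discarded), computes each epoch's log10 band powers,
#' and averages over the previous `r` seconds. One row is produced for each
#' second `t` with full history (`t > r`), labelled with that second's
#' vigilance label.
#'
#' @param recording An [eeg_recording()].
#' @param labels Per-second label vector (+1 alert, -1 drowsy) of length
#'   `n_seconds(recording)`, or `NULL` for unlabelled features.
#' @param channel Channel to featurize.
#' @param r Averaging window in seconds (integer >= 0).
#' @param bands Named list of [rhythm_band()]s.
#' @return Object of class `feature_matrix`: list with `x` (m x n matrix,
#'   one column per band), `y` (labels or `NULL`), `t` (the second index of
#'   each row), `r`, `channel` and `scaling` (`NULL` until scaled).
#' @export
extract_features <- function(recording, labels, channel, r = 0,
                             bands = default_bands()) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!channel %in% recording$channels)
    stop("channel ", channel, " missing from recording")
  if (r < 0 || r != round(r)) stop("r must be a non-negative integer")
  fs <- recording$fs
  total_s <- n_seconds(recording)
  if (!is.null(labels) && length(labels) != total_s)
    stop("label length mismatch: expected ", total_s, ", got ", length(labels))
  if (total_s <= r) stop("recording shorter than the averaging window")
  x <- channel_data(recording, channel)
  psd_series <- lapply(seq_len(total_s), function(t)
    epoch_psd(x[((t - 1) * fs + 1):(t * fs)], fs, epoch_index = t))
  rows_t <- (r + 1):total_s
  feats <- t(vapply(rows_t, function(t) feature_at_time(psd_series, t, r, bands),
                    numeric(length(bands))))
  colnames(feats) <- names(bands)
  structure(list(x = feats,
                 y = if (is.null(labels)) NULL else labels[rows_t],
                 t = rows_t, r = as.integer(r), channel = channel,
                 scaling = NULL),
            class = "feature_matrix")
}

n_rows <- function(fm) nrow(fm$x)

fm_subset <- function(fm, idx) {
  structure(list(x = fm$x[idx, , drop = FALSE],
                 y = if (is.null(fm$y)) NULL else fm$y[idx],
                 t = fm$t[idx], r = fm$r, channel = fm$channel,
                 scaling = fm$scaling),
            class = "feature_matrix")
}

apply_scaling <- function(x, scaling) {
  out <- x
  for (j in seq_len(ncol(x))) {
    lo <- scaling$min[j]; hi <- scaling$max[j]
    out[, j] <- if (hi > lo) 2 * (x[, j] - lo) / (hi - lo) - 1 else 0
  }
  out
}

#' Scale features to [-1, 1] using training-set ranges
#'
#' Each feature dimension is affinely mapped so the *training* column spans
#' `[-1, +1]`; the identical map is applied to `apply_to` (values outside
#' the training range map outside `[-1, 1]`). A constant training column
#' maps to 0 everywhere.
#'
#' @param train Training [extract_features()] matrix.
#' @param apply_to Optional second feature matrix scaled with the training
#'   parameters (e.g. a held-out test block).
#' @return List with `train`, `apply_to` (scaled feature matrices, each
#'   carrying the `scaling` parameters) and `scaling` (data.frame with
#'   per-dimension `min`, `max`).
#' @export
scale_features <- function(train, apply_to = NULL) {
  stopifnot(inherits(train, "feature_matrix"))
  if (n_rows(train) == 0) stop("empty feature matrix")
  scaling <- data.frame(min = apply(train$x, 2, min),
                        max = apply(train$x, 2, max))
  strain <- train
  strain$x <- apply_scaling(train$x, scaling)
  strain$scaling <- scaling
  sapply_to <- NULL
  if (!is.null(apply_to)) {
    sapply_to <- apply_to
    sapply_to$x <- apply_scaling(apply_to$x, scaling)
    sapply_to$scaling <- scaling
  }
  list(train = strain, apply_to = sapply_to, scaling = scaling)
}
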