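# Daubechies-5 analysis/synthesis filter bank (10 taps).
DB5_DEC_LO <- c(3.33572528547377125e-03, -1.25807519990819988e-02,
                -6.24149021279827437e-03, 7.75714938400457188e-02,
                -3.22448695846383748e-02, -2.42294887066382025e-01,
                1.38428145901320743e-01, 7.24308528437772936e-01,
                6.03829269797189649e-01, 1.60102397974192928e-01)
DB5_REC_LO <- rev(DB5_DEC_LO)
DB5_DEC_HI <- rev(DB5_DEC_LO) * rep_len(c(-1, 1), 10) # quadrature mirror
DB5_REC_HI <- rev(DB5_DEC_HI)

WAVELET_LEVELS <- 6L
LEVEL_NAMES <- c("A6", paste0("D", 1:6))

# full linear convolution; direct form beats FFT for a 10-tap filter and
# is immune to awkward transform lengths
conv_full <- function(x, h) {
  L <- length(h)
  z <- c(numeric(L - 1), x, numeric(L - 1))
  y <- stats::filter(z, h, method = "convolution", sides = 1)
  as.numeric(y[L:(2 * L - 2 + length(x))])
}

# one analysis step, symmetric (half-point) boundary extension
dwt_step <- function(x) {
  L <- 10L
  n <- length(x)
  if (n < L - 1) stop("signal too short for db5 analysis")
  ext <- c(x[(L - 1):1], x, x[n:(n - L + 2)])
  nc <- floor((n + L - 1) / 2)
  idx <- seq(L + 1, by = 2, length.out = nc)
  list(a = conv_full(ext, DB5_DEC_LO)[idx],
       d = conv_full(ext, DB5_DEC_HI)[idx])
}

# one synthesis step; result cropped to out_len
idwt_step <- function(a, d, out_len) {
  L <- 10L
  nc <- length(a)
  ua <- numeric(2 * nc); ua[seq(1, 2 * nc, by = 2)] <- a
  ud <- numeric(2 * nc); ud[seq(1, 2 * nc, by = 2)] <- d
  full <- conv_full(ua, DB5_REC_LO) + conv_full(ud, DB5_REC_HI)
  res <- full[(L - 1):(2 * nc)]
  res[seq_len(out_len)]
}

#' Dyadic frequency band of a wavelet detail level
#'
#' Level `j` of an iterated two-channel filter bank covers
#' `(fs / 2^(j+1), fs / 2^j)` Hz. At 512 Hz, D3 = 32-64 Hz, D4 = 16-32 Hz,
#' D5 = 8-16 Hz and D6 = 4-8 Hz, which is why levels D3-D6 jointly carry
#' the 4-64 Hz range containing the theta/alpha/beta rhythms.
#'
#' @param level Detail level, 1-6.
#' @param fs Sampling rate in Hz.
#' @return Numeric `(low, high)` in Hz.
#' @export
#' @examples
#' band_edges(6, 512) # 4-8 Hz, the theta range
band_edges <- function(level, fs) {
  if (length(level) != 1 || level < 1 || level > WAVELET_LEVELS ||
      level != round(level))
    stop("level must be an integer in 1..6")
  if (fs <= 0) stop("fs must be positive")
  c(low = fs / 2^(level + 1), high = fs / 2^level)
}

#' Six-level db5 wavelet decomposition of one channel
#'
#' Decomposes a signal into detail coefficients D1..D6 and the level-6
#' approximation A6 using the Daubechies-5 wavelet with symmetric boundary
#' extension. The full coefficient set reconstructs the input to within
#' numerical precision (see [wavelet_reconstruct()]).
#'
#' @param x Numeric signal of at least 64 samples.
#' @return Object of class `wavelet_decomposition` with elements `wavelet`,
#'   `levels`, `approx` (A6), `details` (list D1..D6), `lengths` (per-level
#'   input lengths, used for reconstruction cropping), `boundary_mode` and
#'   `original_length`.
#' @export
wavelet_decompose <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 64) stop("input too short: need at least 64 samples")
  if (!all(is.finite(x))) stop("input contains non-finite values")
  a <- x
  details <- vector("list", WAVELET_LEVELS)
  lens <- integer(WAVELET_LEVELS)
  for (j in seq_len(WAVELET_LEVELS)) {
    lens[j] <- length(a)
    s <- dwt_step(a)
    details[[j]] <- s$d
    a <- s$a
  }
  names(details) <- paste0("D", seq_len(WAVELET_LEVELS))
  structure(list(wavelet = "db5", levels = WAVELET_LEVELS, approx = a,
                 details = details, lengths = lens,
                 boundary_mode = "symmetric",
                 original_length = length(x)),
            class = "wavelet_decomposition")
}

#' Reconstruct a signal from selected wavelet levels
#'
#' Inverse transform keeping only the named coefficient sequences (the
#' others are zeroed). Keeping all of `A6, D1..D6` reproduces the input;
#' keeping a subset returns that subset's partial reconstruction, and
#' partial reconstructions of disjoint subsets add.
#'
#' @param decomp A [wavelet_decompose()] result.
#' @param keep Character vector, subset of `c("A6", "D1".."D6")`.
#' @return Numeric vector of length `decomp$original_length`.
#' @export
#' @examples
#' x <- rnorm(2048)
#' dec <- wavelet_decompose(x)
#' max(abs(wavelet_reconstruct(dec, c("A6", paste0("D", 1:6))) - x)) < 1e-8
wavelet_reconstruct <- function(decomp, keep = c("D3", "D4", "D5", "D6")) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  unknown <- setdiff(keep, LEVEL_NAMES)
  if (length(unknown) > 0)
    stop("unknown level name(s): ", paste(unknown, collapse = ", "))
  a <- if ("A6" %in% keep) decomp$approx else numeric(length(decomp$approx))
  for (j in rev(seq_len(decomp$levels))) {
    dn <- paste0("D", j)
    d <- if (dn %in% keep) decomp$details[[dn]] else
      numeric(length(decomp$details[[dn]]))
    a <- idwt_step(a, d, decomp$lengths[j])
  }
  a
}

#' Wavelet-denoise an EEG recording
#'
#' Each channel is decomposed with [wavelet_decompose()] and rebuilt from
#' the retained detail levels only (default D3-D6, i.e. 4-64 Hz at 512 Hz).
#' This removes the low-frequency blink band (< 4 Hz, mostly A6) and the
#' high-frequency EMG/noise band (> 64 Hz, D1-D2), without any coefficient
#' thresholding: whole levels are kept or dropped.
#'
#' @param rec An [eeg_recording()].
#' @param keep Levels to retain, default `c("D3","D4","D5","D6")`.
#' @return A denoised [eeg_recording()] with the same fs and channels.
#' @export
denoise <- function(rec, keep = c("D3", "D4", "D5", "D6")) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- rec$data
  for (ch in rec$channels)
    out[, ch] <- wavelet_reconstruct(wavelet_decompose(rec$data[, ch]), keep)
  eeg_recording(out, fs = rec$fs,
                meta = c(rec$meta, list(denoised_keep = keep)))
}
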