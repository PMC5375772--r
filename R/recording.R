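#' Supported 10-20 electrode labels
#'
#' The eight-channel montage used throughout: pre-frontal (Fp1, Fp2),
#' temporal (T3, T4), central (C3, C4) and occipital (O1, O2) sites of the
#' international 10-20 system.
#'
#' @format Character vector of length 8.
#' @export
EEG_MONTAGE <- c("Fp1", "Fp2", "T3", "T4", "C3", "C4", "O1", "O2")

OCCIPITAL_CHANNELS <- c("O1", "O2")
PREFRONTAL_CHANNELS <- c("Fp1", "Fp2")

#' Construct a multi-channel EEG recording
#'
#' Container for an equal-length, regularly sampled multi-channel EEG signal
#' in microvolts. Channels must come from the supported 10-20 montage
#' ([EEG_MONTAGE]) and the recording must hold at least one full second.
#'
#' @param data Numeric matrix (samples x channels) with channel labels as
#'   column names, or a named list of equal-length numeric vectors.
#' @param fs Sampling rate in Hz (default 512).
#' @param meta Optional list of free-form provenance information.
#'
#' @return An object of class `eeg_recording` with elements `fs`, `channels`,
#'   `data` (samples x channels matrix) and `meta`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(1024), ncol = 2,
#'                             dimnames = list(NULL, c("O1", "O2"))), fs = 512)
#' n_seconds(rec)
eeg_recording <- function(data, fs = 512, meta = list()) {
  if (is.list(data) && !is.data.frame(data)) {
    lens <- lengths(data)
    if (length(unique(lens)) != 1L)
      stop("all channels must have equal length")
    data <- do.call(cbind, lapply(data, as.numeric))
  }
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  channels <- colnames(data)
  if (is.null(channels))
    stop("channel labels are required (column names / list names)")
  unknown <- setdiff(channels, EEG_MONTAGE)
  if (length(unknown) > 0)
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(channels))
    stop("duplicate channel labels")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive number")
  if (fs <= 2 * 34)
    stop("fs must exceed twice the highest analysis frequency (34 Hz)")
  if (nrow(data) < fs)
    stop("recording must contain at least one full second of samples")
  if (!all(is.finite(data)))
    stop("recording contains non-finite samples")
  structure(list(fs = fs, channels = channels, data = data, meta = meta),
            class = "eeg_recording")
}

#' Number of whole seconds in a recording
#'
#' @param rec An [eeg_recording()].
#' @return Integer count of complete one-second epochs.
#' @export
n_seconds <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  as.integer(floor(nrow(rec$data) / rec$fs))
}

#' Extract one channel of a recording
#'
#' @param rec An [eeg_recording()].
#' @param channel Channel label.
#' @return Numeric vector of samples in microvolts.
#' @export
channel_data <- function(rec, channel) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!channel %in% rec$channels)
    stop("channel ", channel, " not present in recording")
  rec$data[, channel]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) [%s], %d samples (%.1f s) @ %g Hz\n",
              length(x$channels), paste(x$channels, collapse = ", "),
              nrow(x$data), nrow(x$data) / x$fs, x$fs))
  invisible(x)
}
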