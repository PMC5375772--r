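#' Write a recording to CSV
#'
#' One column per channel (header row = channel labels), samples in
#' microvolts. The sampling rate is not stored in the CSV; supply it again
#' on read. Per-second labels travel in a sidecar TSV (see
#' [write_labels()]).
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.csv(as.data.frame(rec$data), path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' @param path CSV produced by [write_recording_csv()] (header row of
#'   channel labels, one numeric column per channel).
#' @param fs Sampling rate in Hz.
#' @param channels Optional subset of channels to keep.
#' @return An [eeg_recording()].
#' @export
read_recording_csv <- function(path, fs = 512, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) == 0 || !all(colnames(df) %in% EEG_MONTAGE))
    stop("malformed header: expected 10-20 channel labels, got: ",
         paste(utils::head(colnames(df)), collapse = ", "))
  if (!is.null(channels)) df <- df[, channels, drop = FALSE]
  eeg_recording(as.matrix(df), fs = fs, meta = list(source = path))
}

#' Write per-second vigilance labels to a sidecar TSV
#'
#' @param labels Per-second +1/-1 vector.
#' @param path Output TSV path (columns `t`, `label`; `t` is the 1-based
#'   second index).
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(t = seq_along(labels), label = labels),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-second vigilance labels from a sidecar TSV
#'
#' @param path TSV written by [write_labels()].
#' @return Numeric vector of +1/-1 labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label sidecar not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("t", "label") %in% colnames(df)))
    stop("malformed label sidecar: need columns t, label")
  df$label[order(df$t)]
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  edf_pad(s, width)
}

#' Write a recording to EDF (European Data Format)
#'
#' Minimal EDF writer: one signal per channel, physical dimension uV,
#' one-second data records, 16-bit samples. Physical limits are symmetric
#' integers just covering the data range, so amplitude resolution is
#' `2 * limit / 65535` uV. A trailing partial second is dropped (EDF
#' records are whole seconds).
#'
#' @param rec An [eeg_recording()] with integer `fs`.
#' @param path Output `.edf` path.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- as.integer(rec$fs)
  ns <- length(rec$channels)
  n_rec <- n_seconds(rec)
  data <- rec$data[seq_len(n_rec * fs), , drop = FALSE]
  lim <- pmax(ceiling(apply(abs(data), 2, max)), 1)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic subject", 80),
    edf_pad("eegvigil recording", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4),
    paste(vapply(rec$channels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(-lim, edf_num, "", width = 8), collapse = ""),
    paste(vapply(lim, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad("-32768", 8), ns), collapse = ""),
    paste(rep(edf_pad("32767", 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  dig <- matrix(0L, nrow = nrow(data), ncol = ns)
  for (j in seq_len(ns))
    dig[, j] <- as.integer(round((data[, j] + lim[j]) / (2 * lim[j]) *
                                   65535 - 32768))
  dig <- pmin(pmax(dig, -32768L), 32767L)
  for (k in seq_len(n_rec)) {
    idx <- ((k - 1) * fs + 1):(k * fs)
    writeBin(as.integer(dig[idx, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a recording from EDF
#'
#' Reads files written by [write_recording_edf()] and other EDF files with
#' a uniform per-signal sampling rate and recognized 10-20 channel labels.
#'
#' @param path `.edf` file path.
#' @param channels Optional subset of channel labels to keep.
#' @return An [eeg_recording()].
#' @export
read_recording_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8 + 80 + 80 + 8 + 8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns) # transducer
  rd(8 * ns)  # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns) # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  if (length(unique(spr)) != 1) stop("unsupported EDF: mixed sampling rates")
  fs <- spr[1] / rec_dur
  if (!is.finite(fs) || fs <= 0) stop("unsupported sampling rate")
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 endian = "little")
  data <- matrix(0, nrow = n_rec * spr[1], ncol = ns,
                 dimnames = list(NULL, labels))
  pos <- 0
  for (k in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      seg <- raw[(pos + 1):(pos + spr[j])]
      pos <- pos + spr[j]
      phys <- pmin_[j] + (seg - dmin_[j]) * (pmax_[j] - pmin_[j]) /
        (dmax_[j] - dmin_[j])
      data[((k - 1) * spr[j] + 1):(k * spr[j]), j] <- phys
    }
  }
  if (!is.null(channels)) {
    missing_ch <- setdiff(channels, labels)
    if (length(missing_ch) > 0)
      stop("channel(s) absent from EDF: ", paste(missing_ch, collapse = ", "))
    data <- data[, channels, drop = FALSE]
  }
  eeg_recording(data, fs = fs, meta = list(source = path))
}

#' Persist a trained SVM model as versioned JSON
#'
#' @param model A [svm_train()] model.
#' @param path Output `.json` path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "vigil_svm"))
  doc <- list(format = "eegvigil-svm", version = 1L,
              kernel = model$kernel, C = model$C,
              support_vectors = model$support_vectors,
              dual_coefs = model$dual_coefs, alpha = model$alpha,
              sv_labels = model$sv_labels,
              bias = model$bias, dim = model$dim,
              feature_names = model$feature_names,
              scaling = model$scaling, channel = model$channel, r = model$r,
              label_map = as.list(model$label_map),
              objective = model$objective, converged = model$converged)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON model path.
#' @return A `vigil_svm` model; decision values are preserved to 1e-9.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "eegvigil-svm")
    stop("not an eegvigil model file: ", path)
  sv <- matrix(as.numeric(unlist(doc$support_vectors)),
               ncol = doc$dim, byrow = FALSE)
  if (is.matrix(doc$support_vectors)) sv <- doc$support_vectors
  colnames(sv) <- doc$feature_names
  structure(list(kernel = as.list(doc$kernel), C = doc$C,
                 support_vectors = sv,
                 dual_coefs = as.numeric(doc$dual_coefs),
                 alpha = as.numeric(doc$alpha),
                 sv_labels = as.numeric(doc$sv_labels),
                 bias = doc$bias, dim = doc$dim,
                 feature_names = doc$feature_names,
                 scaling = as.data.frame(doc$scaling),
                 channel = doc$channel, r = doc$r,
                 label_map = unlist(doc$label_map),
                 objective = doc$objective, converged = doc$converged),
            class = "vigil_svm")
}

#' Write an evaluation report to TSV or JSON
#'
#' @param report An [r_sweep()] report.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv")
    utils::write.table(report, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  else
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' Run online drowsiness detection over a recording
#'
#' Applies the full pipeline -- denoise, featurize with the model's
#' averaging window, scale with the model's training scaling, classify --
#' to every second with full history, and emits a warning event at each
#' alert-to-drowsy transition (a recording that starts drowsy emits an
#' event at its first classified second). In the deployed system each
#' event would trigger the driver warning.
#'
#' @param recording A raw [eeg_recording()].
#' @param model A [svm_train()] model (carries channel, `r` and scaling).
#' @param r Averaging window; defaults to the model's.
#' @param keep Wavelet levels retained by denoising.
#' @return List with `t` (second indices), `label` (+1/-1 per second),
#'   `decision` (decision values) and `events` (data.frame `t`,
#'   `decision_value`, one row per alert-to-drowsy transition).
#' @export
detect <- function(recording, model, r = model$r,
                   keep = c("D3", "D4", "D5", "D6")) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(model, "vigil_svm"))
  if (n_seconds(recording) < r + 1)
    stop("recording shorter than the averaging window r")
  den <- denoise(recording, keep)
  fm <- extract_features(den, labels = NULL, channel = model$channel, r = r)
  x <- apply_scaling(fm$x, model$scaling)
  dv <- decision_value(model, x)
  lab <- ifelse(dv > 0, 1, -1)
  onset <- which(lab == -1 & c(1, lab[-length(lab)]) == 1)
  list(t = fm$t, label = lab, decision = dv,
       events = data.frame(t = fm$t[onset], decision_value = dv[onset]))
}
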