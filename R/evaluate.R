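#' Confusion counts with drowsy as the positive class
#'
#' Drowsy (-1) is the positive class throughout the evaluation: a true
#' positive is a drowsy second detected as drowsy, a false positive is an
#' alert second flagged drowsy. Centralizing the label-to-class mapping
#' here keeps the `+1 = alert` SVM labelling from leaking sign errors into
#' the statistics.
#'
#' @param predicted,actual Equal-length vectors of +1/-1 labels.
#' @return Object of class `confusion_counts`: list with `tp`, `fn`, `tn`,
#'   `fp` (in seconds).
#' @export
#' @examples
#' confusion(c(-1, -1, 1, 1), c(-1, 1, 1, 1))
confusion <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (length(predicted) == 0) stop("empty vectors")
  if (anyNA(predicted) || anyNA(actual)) stop("NA labels")
  if (!all(c(predicted, actual) %in% c(-1, 1))) stop("labels must be +1/-1")
  structure(list(tp = sum(predicted == -1 & actual == -1),
                 fn = sum(predicted == 1 & actual == -1),
                 tn = sum(predicted == 1 & actual == 1),
                 fp = sum(predicted == -1 & actual == 1)),
            class = "confusion_counts")
}

#' Classification accuracy rate
#'
#' Correctly detected time over total detection time:
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param c A [confusion()] object.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_rate <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) stop("zero total detection time")
  (c$tp + c$tn) / total
}

#' Sensitivity (drowsy detection rate)
#'
#' True positive time over total actual drowsy time: `TP / (TP + FN)`.
#'
#' @param c A [confusion()] object.
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0) stop("no actual drowsy time")
  c$tp / (c$tp + c$fn)
}

#' False positive rate
#'
#' One minus the true-negative fraction of actual alert time:
#' `1 - TN / (TN + FP) = FP / (TN + FP)`.
#'
#' @param c A [confusion()] object.
#' @return False positive rate in `[0, 1]`.
#' @export
false_positive_rate <- function(c) {
  if (c$tn + c$fp == 0) stop("no actual alert time")
  1 - c$tn / (c$tn + c$fp)
}

#' Time-window sweep: evaluate the pipeline for several r values
#'
#' For each averaging window `r`, runs the full detection pipeline on one
#' channel -- wavelet denoising, band-power feature extraction,
#' block-contiguous cross-validated SVM training -- and pools the held-out
#' predictions across blocks (micro-average) into one confusion table per
#' `r`, reporting accuracy, sensitivity and false positive rate, plus the
#' mean wall time per prediction (hardware-dependent; reported, never part
#' of any assertion).
#'
#' @param recording A raw [eeg_recording()] (denoised internally unless
#'   `denoised = TRUE`).
#' @param labels Per-second +1/-1 labels.
#' @param channel Channel to evaluate (default `"O1"`).
#' @param r_values Averaging windows to sweep, default `0:4` seconds.
#' @param config A [training_config()].
#' @param keep Wavelet levels retained by denoising.
#' @param denoised Set `TRUE` if `recording` is already denoised.
#' @return Object of class `evaluation_report` (a data.frame): one row per
#'   `r` with columns `channel`, `r`, `accuracy`, `sensitivity`,
#'   `false_positive_rate`, `tp`, `fn`, `tn`, `fp`, `testing_time_s`.
#' @export
r_sweep <- function(recording, labels, channel = "O1", r_values = 0:4,
                    config = training_config(),
                    keep = c("D3", "D4", "D5", "D6"), denoised = FALSE) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(unique(labels)) < 2) stop("both vigilance states must be present")
  den <- if (denoised) recording else denoise(recording, keep)
  rows <- lapply(r_values, function(r) {
    fm <- extract_features(den, labels, channel, r)
    cv <- cross_validate(fm, config)
    ok <- !is.na(cv$predictions)
    cm <- confusion(cv$predictions[ok], cv$actual[ok])
    data.frame(channel = channel, r = r,
               accuracy = accuracy_rate(cm),
               sensitivity = sensitivity(cm),
               false_positive_rate = false_positive_rate(cm),
               tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp,
               testing_time_s = cv$predict_time_s / sum(ok))
  })
  report <- do.call(rbind, rows)
  attr(report, "config") <- config
  class(report) <- c("evaluation_report", "data.frame")
  report
}

#' Percent view of an evaluation report
#'
#' @param report An [r_sweep()] report with rates in `[0, 1]`.
#' @return The same data.frame with accuracy, sensitivity and false
#'   positive rate expressed in percent.
#' @export
report_percent <- function(report) {
  for (col in c("accuracy", "sensitivity", "false_positive_rate"))
    report[[col]] <- 100 * report[[col]]
  report
}
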