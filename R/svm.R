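#' Training configuration for the vigilance SVM
#'
#' @param C Soft-margin error penalty (> 0); larger values punish margin
#'   violations (the slack variables) more heavily.
#' @param g RBF kernel width parameter (>= 0) in
#'   `exp(-g * ||x - x_i||^2)`.
#' @param kernel One of `"rbf"`, `"linear"`, `"polynomial"`.
#' @param degree,coef0 Polynomial kernel parameters `(x.x_i + coef0)^degree`.
#' @param tolerance Karush-Kuhn-Tucker tolerance of the SMO optimizer.
#' @param max_sweeps Upper bound on optimizer sweeps over the training set.
#' @param grid_C,grid_g Grids searched by [grid_search()]; powers of two in
#'   steps of 2 over C 2^-5..2^15 and g 2^-15..2^3 by default.
#' @param folds Number of contiguous cross-validation blocks (>= 2).
#' @return A list of class `training_config`.
#' @export
training_config <- function(C = 8, g = 1, kernel = c("rbf", "linear", "polynomial"),
                            degree = 3, coef0 = 0, tolerance = 1e-3,
                            max_sweeps = 2000,
                            grid_C = 2^seq(-5, 15, by = 2),
                            grid_g = 2^seq(-15, 3, by = 2),
                            folds = 3) {
  kernel <- match.arg(kernel)
  if (C <= 0) stop("C must be positive")
  if (g < 0) stop("g must be non-negative")
  if (length(grid_C) == 0 || length(grid_g) == 0) stop("grids must be non-empty")
  if (folds < 2) stop("folds must be at least 2")
  structure(list(C = C, g = g, kernel = kernel, degree = degree, coef0 = coef0,
                 tolerance = tolerance, max_sweeps = max_sweeps,
                 grid_C = grid_C, grid_g = grid_g, folds = folds),
            class = "training_config")
}

kernel_type_code <- function(kernel) {
  switch(kernel, linear = 0L, polynomial = 1L, rbf = 2L,
         stop("unknown kernel: ", kernel))
}

#' Evaluate a kernel function between two vectors
#'
#' RBF: `exp(-g * ||x - xi||^2)`; linear: `x . xi`;
#' polynomial: `(x . xi + coef0)^degree`.
#'
#' @param x,xi Numeric vectors of equal length.
#' @param spec List with `kernel` and, as needed, `g`, `coef0`, `degree`
#'   (a [training_config()] works).
#' @return Scalar kernel value.
#' @export
#' @examples
#' kernel_eval(c(0, 0), c(3, 4), list(kernel = "rbf", g = 0.1)) # exp(-2.5)
kernel_eval <- function(x, xi, spec) {
  if (length(x) != length(xi)) stop("dimension mismatch")
  switch(spec$kernel,
         linear = sum(x * xi),
         polynomial = (sum(x * xi) + spec$coef0)^spec$degree,
         rbf = exp(-spec$g * sum((x - xi)^2)),
         stop("unknown kernel: ", spec$kernel))
}

# kernel matrix between rows of A (q x n) and rows of B (p x n)
kernel_matrix <- function(A, B, spec) {
  switch(spec$kernel,
         linear = A %*% t(B),
         polynomial = (A %*% t(B) + spec$coef0)^spec$degree,
         rbf = {
           d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
           exp(-spec$g * pmax(d2, 0))
         },
         stop("unknown kernel: ", spec$kernel))
}

#' Train a soft-margin SVM on a (scaled) feature matrix
#'
#' Solves the dual of the soft-margin SVM by sequential minimal
#' optimization: maximize `sum(a) - 1/2 sum a_i a_j y_i y_j K(x_i, x_j)`
#' subject to `0 <= a_i <= C` and `sum(a_i y_i) = 0`. The decision function
#' is `f(x) = sum over support vectors of a_i y_i K(x_i, x) + b`, with the
#' bias `b` averaged over free support vectors (`0 < a_i < C`).
#'
#' Features are assumed already scaled (see [scale_features()]); the
#' model carries the scaling parameters so new data can be mapped
#' identically at prediction time.
#'
#' @param features A [extract_features()] matrix with labels in {+1, -1}.
#' @param config A [training_config()].
#' @return Object of class `vigil_svm`: kernel spec, `C`,
#'   `support_vectors`, `dual_coefs` (`a_i * y_i`), `alpha`, `bias`,
#'   `scaling`, `channel`, `r`, `label_map`, dual `objective` and
#'   `converged` flag.
#' @export
svm_train <- function(features, config = training_config()) {
  stopifnot(inherits(features, "feature_matrix"))
  X <- features$x
  y <- features$y
  if (is.null(y)) stop("features must be labelled for training")
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1")
  if (length(unique(y)) < 2) stop("single-class training data")
  if (nrow(X) < 2) stop("need at least two training rows")
  if (!all(is.finite(X))) stop("non-finite feature values")
  fit <- smo_fit(X, as.numeric(y), config$C, kernel_type_code(config$kernel),
                 config$g, config$coef0, config$degree,
                 config$tolerance, as.integer(config$max_sweeps))
  sv_idx <- which(fit$alpha > 1e-8)
  structure(list(kernel = list(kernel = config$kernel, g = config$g,
                               coef0 = config$coef0, degree = config$degree),
                 C = config$C,
                 support_vectors = X[sv_idx, , drop = FALSE],
                 dual_coefs = fit$alpha[sv_idx] * y[sv_idx],
                 alpha = fit$alpha[sv_idx],
                 sv_labels = y[sv_idx],
                 bias = fit$b,
                 dim = ncol(X),
                 feature_names = colnames(X),
                 scaling = features$scaling,
                 channel = features$channel,
                 r = features$r,
                 label_map = c(`1` = "alert", `-1` = "drowsy"),
                 objective = fit$objective,
                 converged = fit$converged),
            class = "vigil_svm")
}

#' Pre-sign decision values of an SVM model
#'
#' Returns `sum(a_i y_i K(x_i, x)) + b` for each row of `x` (the argument
#' of the sign in the classification rule). Inputs must already be on the
#' model's feature scale.
#'
#' @param model A [svm_train()] model.
#' @param x Numeric matrix (rows = observations) or single vector.
#' @return Numeric vector of decision values.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "vigil_svm"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$dim) stop("dimension mismatch")
  if (nrow(model$support_vectors) == 0)
    return(rep(model$bias, nrow(x)))
  K <- kernel_matrix(x, model$support_vectors, model$kernel)
  drop(K %*% model$dual_coefs) + model$bias
}

#' Predict vigilance labels
#'
#' Classifies each row as alert (+1) when the decision value is strictly
#' positive, otherwise drowsy (-1). The tie at exactly zero goes to drowsy:
#' for a safety system the fail-safe direction is to warn.
#'
#' @param object A `vigil_svm` model.
#' @param newdata Matrix or vector of observations on the model's feature
#'   scale.
#' @param type `"class"` for +1/-1 labels, `"decision"` for decision values.
#' @param ... Unused.
#' @return Numeric vector of labels or decision values.
#' @export
predict.vigil_svm <- function(object, newdata, type = c("class", "decision"),
                              ...) {
  type <- match.arg(type)
  dv <- decision_value(object, newdata)
  if (type == "decision") return(dv)
  ifelse(dv > 0, 1, -1)
}

# contiguous fold boundaries: m rows into `folds` blocks of near-equal size
cv_blocks <- function(m, folds) {
  bounds <- floor(seq(0, m, length.out = folds + 1))
  lapply(seq_len(folds), function(k) (bounds[k] + 1):bounds[k + 1])
}

#' Block-contiguous cross-validation of the vigilance SVM
#'
#' Partitions the rows into `folds` *contiguous* blocks -- per-second EEG
#' features are serially dependent, so shuffled folds would leak
#' information between train and test. Each block is held out in turn;
#' feature scaling is fitted on the training blocks only. A fold whose
#' training or testing side contains a single class is skipped with a
#' warning.
#'
#' @param features A labelled [extract_features()] matrix (unscaled).
#' @param config A [training_config()].
#' @param folds Number of blocks, default `config$folds`.
#' @return List with `accuracy` (mean over evaluated folds of the fraction
#'   of correctly classified held-out seconds), `fold_accuracy`,
#'   `predictions` (per-row held-out predictions, `NA` for skipped folds),
#'   `actual`, `fold` assignment, and `predict_time_s` (total wall time
#'   spent in prediction).
#' @export
cross_validate <- function(features, config = training_config(),
                           folds = config$folds) {
  stopifnot(inherits(features, "feature_matrix"))
  m <- n_rows(features)
  if (folds < 2) stop("folds must be at least 2")
  if (folds > m) stop("more folds than rows")
  blocks <- cv_blocks(m, folds)
  predictions <- rep(NA_real_, m)
  fold_id <- rep(NA_integer_, m)
  fold_acc <- rep(NA_real_, folds)
  predict_time <- 0
  for (k in seq_len(folds)) {
    te <- blocks[[k]]
    tr <- setdiff(seq_len(m), te)
    fold_id[te] <- k
    if (length(unique(features$y[tr])) < 2) {
      warning("fold ", k, " skipped: training block is single-class")
      next
    }
    sc <- scale_features(fm_subset(features, tr), fm_subset(features, te))
    model <- svm_train(sc$train, config)
    t0 <- proc.time()[["elapsed"]]
    pred <- predict(model, sc$apply_to$x)
    predict_time <- predict_time + (proc.time()[["elapsed"]] - t0)
    predictions[te] <- pred
    fold_acc[k] <- mean(pred == features$y[te])
  }
  if (all(is.na(fold_acc)))
    stop("no fold could be evaluated (single-class blocks)")
  list(accuracy = mean(fold_acc, na.rm = TRUE),
       fold_accuracy = fold_acc,
       predictions = predictions,
       actual = features$y,
       fold = fold_id,
       predict_time_s = predict_time)
}

#' Grid search over (C, g) by cross-validation
#'
#' Evaluates [cross_validate()] accuracy for every pair of the penalty and
#' RBF-width grids and returns the maximizer (ties broken toward the
#' smallest C, then the smallest g) along with the full accuracy surface,
#' suitable for contour plotting.
#'
#' @param features A labelled [extract_features()] matrix.
#' @param config Base [training_config()] (kernel, tolerance, folds).
#' @param grid_C,grid_g Grids, default from `config`.
#' @param folds Number of CV blocks.
#' @return List with `C`, `g`, `accuracy` (best cross-validated accuracy)
#'   and `surface` (data.frame with columns `C`, `g`, `accuracy`).
#' @export
grid_search <- function(features, config = training_config(),
                        grid_C = config$grid_C, grid_g = config$grid_g,
                        folds = config$folds) {
  if (length(grid_C) == 0 || length(grid_g) == 0) stop("grids must be non-empty")
  grid_C <- sort(grid_C)
  grid_g <- sort(grid_g)
  surface <- expand.grid(C = grid_C, g = grid_g, KEEP.OUT.ATTRS = FALSE)
  surface$accuracy <- NA_real_
  best <- list(C = NA_real_, g = NA_real_, accuracy = -Inf)
  for (i in seq_len(nrow(surface))) {
    cfg <- config
    cfg$C <- surface$C[i]
    cfg$g <- surface$g[i]
    acc <- cross_validate(features, cfg, folds)$accuracy
    surface$accuracy[i] <- acc
    better <- acc > best$accuracy + 1e-12 ||
      (abs(acc - best$accuracy) <= 1e-12 &&
         (surface$C[i] < best$C ||
            (surface$C[i] == best$C && surface$g[i] < best$g)))
    if (better) best <- list(C = surface$C[i], g = surface$g[i], accuracy = acc)
  }
  list(C = best$C, g = best$g, accuracy = best$accuracy, surface = surface)
}
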