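# Independent oracles used across the suite. Everything here is written
# against the mathematical definitions, not against the package's code
# paths, so agreement is evidence and not tautology.

# kernel matrix straight from the definitions
oracle_kernel <- function(X, spec) {
  m <- nrow(X)
  K <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (spec$kernel == "rbf")
      K[i, j] <- exp(-spec$g * sum((X[i, ] - X[j, ])^2))
    else if (spec$kernel == "linear")
      K[i, j] <- sum(X[i, ] * X[j, ])
    else
      K[i, j] <- (sum(X[i, ] * X[j, ]) + spec$coef0)^spec$degree
  }
  K
}

# W(a) = sum(a) - 1/2 a' Q a with Q = (y y') * K
dual_objective <- function(alpha, K, y) {
  Q <- (y %o% y) * K
  sum(alpha) - 0.5 * drop(t(alpha) %*% Q %*% alpha)
}

# independent solver of the SVM dual
#   max sum(a) - 1/2 a' Q a  s.t.  0 <= a <= C, sum(a * y) = 0
# via quadprog's Goldfarb-Idnani active-set method (an entirely different
# algorithm family from sequential minimal optimization). A tiny ridge keeps
# the Hessian positive definite when K is singular (e.g. linear kernels);
# its effect on the objective is many orders below the comparison tolerance.
oracle_dual_qp <- function(K, y, C) {
  m <- length(y)
  Q <- (y %o% y) * K
  ridge <- 1e-10 * (sum(diag(Q)) / m) + 1e-12
  sol <- quadprog::solve.QP(Q + diag(ridge, m), rep(1, m),
                            cbind(y, diag(m), -diag(m)),
                            c(0, rep(0, m), rep(-C, m)), meq = 1)
  pmin(pmax(sol$solution, 0), C)
}

# KKT residuals of a trained model at its own training points
kkt_violation <- function(model, X, y, C) {
  f <- decision_value(model, X)
  a <- numeric(nrow(X))
  sv_rows <- apply(model$support_vectors, 1, function(s)
    which(apply(X, 1, function(r) all(abs(r - s) < 1e-12)))[1])
  a[sv_rows] <- model$alpha
  yf <- y * f
  worst <- 0
  for (i in seq_along(y)) {
    v <- if (a[i] < 1e-6) max(0, 1 - yf[i])          # a = 0  -> y f >= 1
    else if (a[i] > C - 1e-6) max(0, yf[i] - 1)      # a = C  -> y f <= 1
    else abs(yf[i] - 1)                              # free   -> y f  = 1
    worst <- max(worst, v)
  }
  worst
}

# Hann-windowed Welch estimate of linear band power (mean over segments)
welch_band_power <- function(x, fs, lo, hi, win = 2 * fs) {
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  ns <- floor(length(x) / win)
  tot <- 0
  for (t in seq_len(ns)) {
    seg <- x[((t - 1) * win + 1):(t * win)] * w
    p <- Mod(stats::fft(seg))^2 / (win * sum(w^2))
    nb <- win / 2 + 1
    p <- p[1:nb]
    p[2:(nb - 1)] <- 2 * p[2:(nb - 1)]
    f <- (0:(win / 2)) * fs / win
    tot <- tot + sum(p[f >= lo & f < hi])
  }
  tot / ns
}

# log-log periodogram slope over 3-100 Hz, averaged over 1-s segments
psd_slope <- function(x, fs) {
  ns <- floor(length(x) / fs)
  acc <- 0
  for (t in seq_len(ns))
    acc <- acc + Mod(stats::fft(x[((t - 1) * fs + 1):(t * fs)]))^2
  p <- acc[2:(fs / 2)]
  f <- seq_len(fs / 2 - 1)
  k <- f >= 3 & f <= 100
  unname(stats::coef(stats::lm(log10(p[k]) ~ log10(f[k])))[2])
}

# feature_matrix built directly from numbers (for SVM unit tests)
make_fm <- function(x, y, r = 0L, channel = "O1") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, y = y, t = seq_len(nrow(x)), r = as.integer(r),
                 channel = channel, scaling = NULL),
            class = "feature_matrix")
}

# small two-class fixture problems (m <= 8) for dual-oracle comparison
svm_fixtures <- function() {
  set.seed(4242)
  fx <- list(
    list(name = "separable-linear",
         X = rbind(c(0, 0), c(0, 1), c(3, 0), c(3, 1)),
         y = c(-1, -1, 1, 1), config = training_config(C = 1000, kernel = "linear")),
    list(name = "xor-rbf",
         X = rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0)),
         y = c(1, 1, -1, -1), config = training_config(C = 10, g = 1)),
    list(name = "random-rbf-6",
         X = matrix(rnorm(12), 6, 2),
         y = c(1, 1, 1, -1, -1, -1), config = training_config(C = 5, g = 0.7)),
    list(name = "random-linear-8",
         X = matrix(rnorm(16), 8, 2),
         y = rep(c(1, -1), 4), config = training_config(C = 2, kernel = "linear")),
    list(name = "unbalanced-rbf",
         X = matrix(rnorm(16, sd = 2), 8, 2),
         y = c(1, 1, -1, -1, -1, -1, -1, -1), config = training_config(C = 3, g = 0.3)),
    list(name = "overlapping-rbf",
         X = rbind(matrix(rnorm(8, 0, 1), 4, 2), matrix(rnorm(8, 0.5, 1), 4, 2)),
         y = c(rep(1, 4), rep(-1, 4)), config = training_config(C = 1, g = 2))
  )
  fx
}
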