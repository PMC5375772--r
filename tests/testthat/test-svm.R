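test_that("kernel evaluations follow their closed forms", {
  expect_equal(kernel_eval(c(1, 2), c(1, 2), list(kernel = "rbf", g = 3.7)), 1)
  expect_equal(kernel_eval(c(0, 1), c(5, -2), list(kernel = "rbf", g = 0)), 1)
  expect_equal(kernel_eval(c(0, 0), c(3, 4), list(kernel = "rbf", g = 0.1)),
               exp(-2.5))
  expect_equal(kernel_eval(c(1, 2), c(3, 4), list(kernel = "linear")), 11)
  expect_equal(kernel_eval(c(1, 0), c(2, 0),
                           list(kernel = "polynomial", coef0 = 1, degree = 3)),
               27)
  expect_error(kernel_eval(c(1, 2), c(1, 2, 3), list(kernel = "linear")),
               "dimension mismatch")
})

test_that("the RBF Gram matrix is positive semidefinite on distinct points", {
  set.seed(31)
  X <- matrix(rnorm(40), 20, 2)
  K <- oracle_kernel(X, list(kernel = "rbf", g = 1.3))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("a separable linear problem recovers the maximum-margin plane", {
  fm <- make_fm(rbind(c(0, 0), c(0, 1), c(3, 0), c(3, 1)), c(-1, -1, 1, 1))
  m <- svm_train(fm, training_config(C = 1000, kernel = "linear"))
  expect_equal(decision_value(m, fm$x), c(-1, -1, 1, 1), tolerance = 1e-2)
  expect_equal(decision_value(m, c(1.5, 0.5)), 0, tolerance = 1e-2)
  # geometric margin equals 2/||w||, here the class separation of 3
  w <- colSums(m$dual_coefs * m$support_vectors)
  expect_equal(2 / sqrt(sum(w^2)), 3, tolerance = 1e-2)
})

test_that("the RBF kernel solves XOR perfectly", {
  fm <- make_fm(rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0)), c(1, 1, -1, -1))
  m <- svm_train(fm, training_config(C = 10, g = 1))
  expect_equal(mean(predict(m, fm$x) == fm$y), 1)
})

test_that("trained duals are feasible, KKT-satisfying and oracle-equivalent", {
  for (fx in svm_fixtures()) {
    m <- svm_train(make_fm(fx$X, fx$y), fx$config)
    C <- fx$config$C
    # dual feasibility
    expect_true(all(m$alpha > 0), info = fx$name)
    expect_true(all(m$alpha <= C + 1e-8), info = fx$name)
    expect_lt(abs(sum(m$dual_coefs)), 1e-6) # sum a_i y_i = 0
    # KKT satisfaction at tolerance
    expect_lt(kkt_violation(m, fx$X, fx$y, C), 1e-2)
    # objective matches the active-set QP oracle
    K <- oracle_kernel(fx$X, fx$config)
    a_star <- oracle_dual_qp(K, fx$y, C)
    expect_equal(m$objective, dual_objective(a_star, K, fx$y),
                 tolerance = 1e-3, info = fx$name)
  }
})

test_that("training rejects degenerate inputs", {
  fm <- make_fm(matrix(rnorm(8), 4, 2), c(1, 1, 1, 1))
  expect_error(svm_train(fm), "single-class")
  bad <- make_fm(matrix(c(NA, rnorm(7)), 4, 2), c(1, 1, -1, -1))
  expect_error(svm_train(bad), "non-finite")
})

test_that("flipping all labels negates every decision value", {
  set.seed(15)
  X <- matrix(rnorm(24), 12, 2)
  y <- rep(c(1, -1), 6)
  cfg <- training_config(C = 4, g = 0.8)
  m1 <- svm_train(make_fm(X, y), cfg)
  m2 <- svm_train(make_fm(X, -y), cfg)
  probe <- matrix(rnorm(10), 5, 2)
  expect_equal(decision_value(m1, probe), -decision_value(m2, probe),
               tolerance = 1e-6)
})

test_that("prediction breaks ties toward drowsy", {
  # degenerate model with no support vectors: decision value is the bias
  m <- structure(list(kernel = list(kernel = "rbf", g = 1), C = 1,
                      support_vectors = matrix(numeric(0), 0, 2),
                      dual_coefs = numeric(0), alpha = numeric(0),
                      bias = 0, dim = 2L, scaling = NULL),
                 class = "vigil_svm")
  expect_identical(decision_value(m, c(1, 1)), 0)
  expect_identical(predict(m, c(1, 1)), -1)
  m$bias <- 0.5
  expect_identical(predict(m, c(1, 1)), 1)
  m$bias <- -0.5
  expect_identical(predict(m, c(1, 1)), -1)
})

test_that("training accuracy does not decrease with C", {
  set.seed(60)
  X <- rbind(matrix(rnorm(40, -0.6), 20, 2), matrix(rnorm(40, 0.6), 20, 2))
  y <- rep(c(-1, 1), each = 20)
  fm <- make_fm(X, y)
  accs <- vapply(2^(-4:6), function(C) {
    m <- svm_train(fm, training_config(C = C, g = 1))
    mean(predict(m, X) == y)
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-12))
})

test_that("decision values agree with an independent SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(99)
  X <- rbind(matrix(rnorm(60, -0.8), 30, 2), matrix(rnorm(60, 0.8), 30, 2))
  y <- rep(c(-1, 1), each = 30)
  cfg <- training_config(C = 2, g = 0.5)
  mine <- svm_train(make_fm(X, y), cfg)
  ref <- e1071::svm(X, factor(y), scale = FALSE, kernel = "radial",
                    cost = 2, gamma = 0.5)
  dv_ref <- attr(predict(ref, X, decision.values = TRUE), "decision.values")
  sgn <- if (colnames(dv_ref)[1] == "-1/1") -1 else 1
  expect_equal(decision_value(mine, X), sgn * as.numeric(dv_ref),
               tolerance = 1e-2)
})

test_that("contiguous cross-validation separates what it should", {
  set.seed(7)
  # strongly separated classes, alternating blocks so folds stay two-class
  X <- rbind(matrix(rnorm(60, -3), 30, 2), matrix(rnorm(60, 3), 30, 2),
             matrix(rnorm(60, -3), 30, 2), matrix(rnorm(60, 3), 30, 2))
  y <- rep(c(-1, 1, -1, 1), each = 30)
  cv <- cross_validate(make_fm(X, y), training_config(C = 8, g = 1), folds = 3)
  expect_equal(cv$accuracy, 1)
  expect_true(all(!is.na(cv$predictions)))
  # permuted labels: accuracy near chance
  set.seed(8)
  Xn <- matrix(rnorm(600), 300, 2)
  yn <- rep(rep(c(1, -1), each = 10), 15) # balanced within each block
  cvn <- cross_validate(make_fm(Xn, yn), training_config(C = 8, g = 1), folds = 3)
  expect_gt(cvn$accuracy, 0.4)
  expect_lt(cvn$accuracy, 0.6)
})

test_that("single-class training blocks are skipped with a warning", {
  X <- matrix(rnorm(24), 12, 2)
  y <- c(rep(1, 4), rep(-1, 4), rep(1, 4))
  # fold 2's complement is all +1 -> skipped
  expect_warning(cv <- cross_validate(make_fm(X, y),
                                      training_config(C = 1, g = 1), folds = 3),
                 "single-class")
  expect_true(is.na(cv$fold_accuracy[2]))
  expect_true(all(is.na(cv$predictions[5:8])))
})

test_that("grid search returns the accuracy maximizer and full surface", {
  set.seed(3)
  X <- rbind(matrix(rnorm(60, -2), 30, 2), matrix(rnorm(60, 2), 30, 2),
             matrix(rnorm(60, -2), 30, 2), matrix(rnorm(60, 2), 30, 2))
  y <- rep(c(-1, 1, -1, 1), each = 30)
  fm <- make_fm(X, y)
  one <- grid_search(fm, training_config(), grid_C = 8, grid_g = 1)
  expect_equal(one$C, 8)
  expect_equal(one$g, 1)
  gs <- grid_search(fm, training_config(), grid_C = 2^c(-1, 3, 7),
                    grid_g = 2^c(-3, 0))
  expect_equal(nrow(gs$surface), 6)
  expect_true(all(gs$surface$accuracy >= 0 & gs$surface$accuracy <= 1))
  expect_gte(gs$accuracy, 0.95)
  # ties break toward the smallest C, then smallest g
  top <- gs$surface[abs(gs$surface$accuracy - gs$accuracy) <= 1e-12, ]
  expect_equal(gs$C, min(top$C))
  expect_equal(gs$g, min(top$g[top$C == gs$C]))
})
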