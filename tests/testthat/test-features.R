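fs <- 512
tt <- (0:(fs - 1)) / fs

test_that("epoch PSD peaks at the tone frequency and scales with power", {
  p10 <- epoch_psd(sin(2 * pi * 10 * tt), fs)
  expect_equal(p10$freqs[which.max(p10$psd)], 10)
  p20 <- epoch_psd(2 * sin(2 * pi * 10 * tt), fs)
  expect_equal(max(p20$log_psd) - max(p10$log_psd), log10(4), tolerance = 1e-9)
  z <- epoch_psd(numeric(fs), fs)
  expect_true(all(z$log_psd == -12))
  expect_length(p10$freqs, fs / 2 + 1)
  expect_error(epoch_psd(numeric(100), fs), "exactly fs")
})

test_that("white-noise one-sided power satisfies Parseval within 15%", {
  set.seed(123)
  tot <- mean(replicate(100, sum(epoch_psd(rnorm(fs), fs)$psd)))
  expect_equal(tot, 1, tolerance = 0.15)
})

test_that("band power sums linear bins over half-open intervals", {
  mkpsd <- function(lin) {
    structure(list(epoch_index = 1L, freqs = 0:(fs / 2), psd = lin,
                   log_psd = log10(pmax(lin, 1e-12))), class = "epoch_psd")
  }
  bands <- default_bands()
  lin <- numeric(fs / 2 + 1)
  lin[6 + 1] <- 0.25 # single bin at 6 Hz
  p <- mkpsd(lin)
  expect_equal(band_power(p, bands$theta), log10(0.25))
  expect_equal(band_power(p, bands$alpha), -12)
  expect_equal(band_power(p, bands$beta), -12)
  # a bin exactly at 8 Hz belongs to alpha, not theta
  lin8 <- numeric(fs / 2 + 1)
  lin8[8 + 1] <- 1
  expect_equal(band_power(mkpsd(lin8), bands$alpha), 0)
  expect_equal(band_power(mkpsd(lin8), bands$theta), -12)
  # uniform unit spectrum: theta = bins 4,5,6,7 -> log10(4)
  expect_equal(band_power(mkpsd(rep(1, fs / 2 + 1)), bands$theta), log10(4))
  expect_error(band_power(p, rhythm_band("hf", 200, 400)), "outside")
  # theta/alpha/beta bins partition [4, 34) at 1 Hz resolution
  f <- 0:(fs / 2)
  members <- lapply(bands, function(b) f[f >= b$low & f < b$high])
  expect_equal(sort(unname(unlist(members))), 4:33)
  expect_equal(sum(lengths(members)), 30)
})

test_that("time-window averaging is an inclusive mean over r+1 epochs", {
  mk <- function(v) {
    lin <- numeric(fs / 2 + 1)
    lin[6 + 1] <- v
    structure(list(epoch_index = 1L, freqs = 0:(fs / 2), psd = lin,
                   log_psd = log10(pmax(lin, 1e-12))), class = "epoch_psd")
  }
  series <- lapply(c(10, 100, 1000), mk) # theta log powers 1, 2, 3
  v <- feature_at_time(series, t = 3, r = 2)
  expect_equal(unname(v[["theta"]]), 2)
  expect_equal(feature_at_time(series, 2, 0)[["theta"]], 2)
  # constant series: any r gives the same vector
  const <- lapply(rep(10, 5), mk)
  for (r in 0:4)
    expect_equal(feature_at_time(const, 5, r), feature_at_time(const, 5, 0))
  expect_error(feature_at_time(series, t = 2, r = 2), "insufficient history")
})

test_that("averaging preserves per-epoch ordering of band powers", {
  set.seed(5)
  mkr <- function(base) {
    lin <- numeric(fs / 2 + 1)
    lin[5:8] <- base + runif(4)
    structure(list(epoch_index = 1L, freqs = 0:(fs / 2), psd = lin,
                   log_psd = log10(pmax(lin, 1e-12))), class = "epoch_psd")
  }
  A <- lapply(rep(10, 8), mkr) # every epoch's theta power above B's
  B <- lapply(rep(1, 8), mkr)
  for (t in 5:8) for (r in 0:3)
    expect_gt(feature_at_time(A, t, r)[["theta"]],
              feature_at_time(B, t, r)[["theta"]])
})

test_that("feature extraction yields one row per second with full history", {
  sim <- generate_recording(state_schedule(c("alert", "drowsy"), c(60, 60)),
                            channels = "O1", seed = 8)
  fm4 <- extract_features(sim$recording, sim$labels, "O1", r = 4)
  expect_equal(nrow(fm4$x), 116)
  expect_identical(fm4$y, sim$labels[5:120])
  fm0 <- extract_features(sim$recording, sim$labels, "O1", r = 0)
  expect_equal(nrow(fm0$x), 120)
  expect_error(extract_features(sim$recording, sim$labels, "C3", 0), "missing")
  expect_error(extract_features(sim$recording, sim$labels[-1], "O1", 0),
               "label length mismatch")
})

test_that("drowsy seconds carry more occipital theta/alpha than alert ones", {
  sim <- generate_recording(alternating_schedule(300, 3), channels = "O1",
                            seed = 21)
  den <- denoise(sim$recording)
  fm <- extract_features(den, sim$labels, "O1", r = 0)
  drowsy <- fm$y == -1
  expect_gt(mean(fm$x[drowsy, "theta"]), mean(fm$x[!drowsy, "theta"]))
  expect_gt(mean(fm$x[drowsy, "alpha"]), mean(fm$x[!drowsy, "alpha"]))
  # the beta decrease is masked at the 14-16 Hz edge by Hann-mainlobe
  # leakage from the (4x stronger) drowsy alpha in one-second epochs, so
  # measure it on the leakage-free band interior
  core <- extract_features(den, sim$labels, "O1", r = 0,
                           bands = list(theta = rhythm_band("theta", 4, 8),
                                        alpha = rhythm_band("alpha", 8, 14),
                                        beta = rhythm_band("beta_core", 16, 30)))
  expect_lt(mean(core$x[drowsy, "beta"]), mean(core$x[!drowsy, "beta"]))
  # the contrasts are statistically solid over ~300 epochs per state
  expect_lt(t.test(fm$x[!drowsy, "theta"], fm$x[drowsy, "theta"])$p.value, 1e-6)
})

test_that("feature scaling maps training ranges to [-1, 1]", {
  tr <- make_fm(cbind(a = c(2, 4, 3), b = c(1, 1, 1)), y = c(1, -1, 1))
  te <- make_fm(cbind(a = c(4, 2, 5), b = c(7, 0, 1)), y = c(1, -1, 1))
  sc <- scale_features(tr, te)
  expect_equal(sc$train$x[, "a"], c(-1, 1, 0))
  expect_equal(sc$train$x[, "b"], c(0, 0, 0)) # constant column -> 0
  expect_equal(sc$apply_to$x[, "a"], c(1, -1, 2)) # training max -> +1
  expect_equal(sc$apply_to$x[, "b"], c(0, 0, 0))
  expect_error(scale_features(make_fm(matrix(numeric(0), 0, 2), numeric(0))),
               "empty")
})
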