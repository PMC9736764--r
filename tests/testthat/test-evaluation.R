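test_that("SNR follows the power-ratio definition and its exact identity", {
  rep <- snr_report(c(2, -2, 2, -2), c(3, -1, 3, -1), c(2.5, -1.5, 2.5, -1.5))
  expect_equal(rep$snr_in, 10 * log10(16 / 4), tolerance = 1e-12)
  expect_equal(rep$snr_in, 6.0206, tolerance = 1e-4)
  expect_equal(rep$snr_out, 12.0412, tolerance = 1e-4)
  expect_equal(rep$snr_imp, rep$snr_out - rep$snr_in)  # bit-exact identity
  # no-op denoising has exactly zero improvement
  rep0 <- snr_report(c(2, -2, 2, -2), c(3, -1, 3, -1), c(3, -1, 3, -1))
  expect_identical(rep0$snr_imp, 0)
  # common scaling leaves all three values unchanged
  reps <- snr_report(5 * c(2, -2, 2, -2), 5 * c(3, -1, 3, -1),
                     5 * c(2.5, -1.5, 2.5, -1.5))
  expect_equal(reps$snr_in, rep$snr_in, tolerance = 1e-12)
  expect_equal(reps$snr_out, rep$snr_out, tolerance = 1e-12)
  # degenerate inputs
  expect_warning(r <- snr_report(1:4, 1:4, c(1, 2, 3, 5)), "infinite")
  expect_identical(r$snr_in, Inf)
  expect_error(snr_report(rep(0, 4), 1:4, 1:4), "zero")
})

test_that("the warp cost matches exhaustive path enumeration", {
  r <- dtw(c(1, 2, 3), c(1, 3))
  expect_equal(r$total_cost, 1)
  same <- dtw(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$total_cost, 0)
  expect_equal(same$percent_distance, 0)
  expect_equal(same$path, cbind(1:3, 1:3))
  # random pairs over {0,1,2}, lengths up to 5, against the brute-force oracle
  set.seed(31)
  for (i in 1:60) {
    a <- sample(0:2, sample(2:5, 1), replace = TRUE)
    b <- sample(0:2, sample(2:5, 1), replace = TRUE)
    expect_equal(dtw(a, b, require_percent = FALSE)$total_cost,
                 brute_dtw_cost(a, b))
  }
  # symmetry for equal lengths
  a <- c(0, 2, 1, 1, 2); b <- c(2, 0, 0, 1, 2)
  expect_equal(dtw(a, b, require_percent = FALSE)$total_cost,
               dtw(b, a, require_percent = FALSE)$total_cost)
  expect_error(dtw(rep(1, 5), c(1, 2)), "constant reference")
  # path endpoints and admissible steps
  p <- dtw(c(0, 1, 2, 1), c(1, 2, 0))$path
  expect_equal(p[1, ], c(1, 1))
  expect_equal(p[nrow(p), ], c(4, 3))
  steps <- diff(p)
  expect_true(all(steps %in% 0:1) && all(rowSums(steps) >= 1))
})

test_that("the cross-correlation index scales as sqrt(N) for self-comparison", {
  set.seed(32)
  x <- rnorm(100)
  expect_equal(cross_correlation_index(x, x), 10, tolerance = 1e-9)
  tt <- (0:999) / 250
  # quadrature pair on the zero-lag grid is orthogonal
  expect_lt(abs(cross_correlation_index(sin(2 * pi * 5 * tt),
                                        cos(2 * pi * 5 * tt),
                                        max_lag_frac = 0)), 0.1)
  expect_warning(z <- cross_correlation_index(rep(0, 50), rnorm(50)), "zero-variance")
  expect_identical(z, 0)
})

test_that("feature differences and similarities follow the percent rule", {
  rest <- default_rest_features()
  fd0 <- feature_difference(rest, rest)
  expect_true(all(fd0$percent == 0))
  expect_true(all(fd0$similarity == 1))
  up <- rest; up$a_R <- 1.5 * rest$a_R
  fd1 <- feature_difference(rest, up)
  expect_equal(unname(fd1$percent["a_R"]), 50)
  expect_equal(unname(fd1$similarity["a_R"]), 0.5)
  # similarity of a reported 3.24% difference
  fd2 <- feature_diff_from_percent(c(10, 10, 10, 3.24, 10, 10, 10, 10))
  expect_equal(unname(fd2$similarity["a_R"]), 0.9676)
  # clamping at >100% difference
  fd3 <- feature_diff_from_percent(c(150, rep(10, 7)))
  expect_equal(unname(fd3$similarity["a_P"]), 0)
  # zero resting feature is excluded and flagged
  rest0 <- rest; rest0$a_P <- 0
  fd4 <- feature_difference(rest0, rest)
  expect_true("a_P" %in% fd4$excluded)
  expect_true(is.na(fd4$percent["a_P"]))
})

test_that("the WDA index is a normalized weighted projection of similarities", {
  all1 <- feature_diff_from_percent(rep(0, 8))
  expect_equal(wda(all1, wda_weights("equal")), 8 / sqrt(8), tolerance = 1e-12)
  all0 <- feature_diff_from_percent(rep(100, 8))
  expect_equal(wda(all0), 0)
  # monotone in every similarity entry with positive weight
  base <- feature_diff_from_percent(rep(50, 8))
  for (i in 1:8) {
    pct <- rep(50, 8); pct[i] <- 40
    expect_gt(wda(feature_diff_from_percent(pct)), wda(base))
  }
  # joint weight rescaling cancels
  d <- feature_diff_from_percent(c(20, 35, 10, 5, 50, 60, 15, 25))
  expect_equal(wda(d, rep(1, 8)), wda(d, rep(0.5, 8)), tolerance = 1e-12)
  expect_error(wda(d, rep(0, 8)), "zero")
  expect_error(wda(d, rep(2, 8)), "\\[0, 1\\]")
  inc <- feature_diff_from_percent(c(NA, rep(10, 7)))
  expect_error(wda(inc), "incomplete")
  # presets
  expect_equal(unname(wda_weights("qrs_amplitude")[4]), 0.9)
  expect_equal(unname(wda_weights("qrs_amplitude")[1]), 0.5)
})

test_that("the full evaluation report runs end to end on a denoised fixture", {
  sim <- sim_fixture(snr = -5, seed = 11)
  f <- default_rest_features()
  res <- rdica_denoise(sim$record, "DII", f, seed = 1)
  rep <- evaluate_denoising(sim$record$data[, 1], res$denoised, 250, f,
                            clean = sim$truth$clean_ecg)
  expect_gt(rep$snr$snr_imp, 0)
  expect_true(is.finite(rep$dtw_percent) && rep$dtw_percent >= 0)
  expect_true(is.finite(rep$cross_correlation))
  expect_length(rep$wda, 4)
  # EA-proxy fallback path
  rep2 <- evaluate_denoising(sim$record$data[, 1], res$denoised, 250, f)
  expect_identical(rep2$snr$clean_source, "EA-proxy")
})
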