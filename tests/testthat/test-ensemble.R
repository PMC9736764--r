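test_that("R peaks are found on a known train with unit gaps and fail on flat input", {
  x <- clean_train(60, 30)
  pk <- detect_r_peaks(x, 250)
  expect_length(pk$indices, 30)
  expect_true(all(abs(diff(pk$indices) - 250) <= 1))
  expect_error(detect_r_peaks(rep(0, 2500), 250), "no peaks")
  expect_error(detect_r_peaks(rnorm(100), 250), "at least 2 s")
})

test_that("polarity auto-detection handles an inverted lead", {
  x <- clean_train(60, 30)
  up <- detect_r_peaks(x, 250)
  dn <- detect_r_peaks(-x, 250)
  expect_equal(length(dn$indices), length(up$indices))
  expect_identical(dn$polarity, "down")
  expect_equal(dn$indices, up$indices, tolerance = 0)
})

test_that("the ensemble of identical beats has zero SD and the single-beat mean", {
  x <- clean_train(60, 30)
  pk <- detect_r_peaks(x, 250)
  ens <- ensemble_average(x, pk)
  expect_true(all(ens$sd_beat == 0))
  i <- pk$indices[5]
  n_pre <- ens$fiducial_index - 1L
  one <- x[(i - n_pre):(i - n_pre + length(ens$mean_beat) - 1L)]
  expect_equal(ens$mean_beat, one, tolerance = 1e-12)
})

test_that("averaging n beats shrinks independent noise as 1/sqrt(n)", {
  m <- model_hr(60)
  x <- synthesize_ecg(m, 102, 0)
  set.seed(99)
  xn <- x + rnorm(length(x), 0, 0.05)
  pk <- detect_r_peaks(xn, 250)
  ens <- ensemble_average(xn, pk)
  # the 0.4/0.6 RR window of a 60 bpm train lands exactly on the template grid
  clean_beat <- synthesize_beat(m)$samples
  expect_gte(ens$n_beats, 95)
  expect_lt(mean(abs(ens$mean_beat - clean_beat[seq_along(ens$mean_beat)])), 0.015)
})

test_that("beats whose window leaves the record are discarded", {
  x <- clean_train(60, 30)
  pk <- detect_r_peaks(x, 250)
  pk2 <- pk
  pk2$indices <- c(3L, pk$indices)  # fake beat at the very start
  pk2$times <- (pk2$indices - 1) / 250
  ens_full <- ensemble_average(x, pk)
  ens_edge <- ensemble_average(x, pk2)
  expect_equal(ens_edge$n_beats, ens_full$n_beats)
})

test_that("extracted features recover the generator's coefficients", {
  f <- default_rest_features()
  fe <- rest_features_from_signal(clean_train(60, 30), 250)
  expect_lt(abs(fe$a_R - f$a_R) / f$a_R, 0.02)
  expect_lt(abs(fe$a_P - f$a_P) / f$a_P, 0.03)
  expect_lt(abs(fe$a_T - f$a_T) / f$a_T, 0.03)
  expect_lt(abs(fe$t_P_R - f$t_P_R), 0.010)
  expect_lt(abs(fe$t_R_T - f$t_R_T), 0.010)
})

test_that("feature extraction respects scaling, offsets and absent waves", {
  x <- clean_train(60, 30)
  pk <- detect_r_peaks(x, 250)
  ens <- ensemble_average(x, pk)
  fe <- extract_features(ens)
  # amplitude linearity
  ens2 <- ens; ens2$mean_beat <- 2 * ens$mean_beat; ens2$sd_beat <- 2 * ens$sd_beat
  fe2 <- extract_features(ens2)
  expect_equal(fe2$a_R, 2 * fe$a_R, tolerance = 1e-9)
  expect_equal(fe2$a_P, 2 * fe$a_P, tolerance = 1e-9)
  expect_equal(fe2$t_P_R, fe$t_P_R)
  expect_equal(fe2$d_T, fe$d_T)
  # offset invariance (baseline subtraction)
  ens3 <- ens; ens3$mean_beat <- ens$mean_beat + 0.7
  fe3 <- extract_features(ens3)
  expect_equal(fe3$a_R, fe$a_R, tolerance = 1e-9)
  # absent P wave
  f0 <- ecg_features(a_P = 0, d_P = NA, t_P_R = NA, a_R = 1, d_R = 0.09,
                     t_R_T = 0.3, a_T = 0.3, d_T = 0.16)
  x0 <- synthesize_ecg(template_from_features(f0, 60, 250), 30, 0)
  fe0 <- rest_features_from_signal(x0, 250)
  expect_equal(fe0$a_P, 0)
  expect_true(is.na(fe0$d_P))
})
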