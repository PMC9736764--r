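test_that("a single raised-cosine segment peaks at its amplitude and stays local", {
  m <- beat_model(data.frame(label = "R", amp = 1, dur = 0.1, onset = 0.4),
                  period = 1, fs = 250)
  b <- synthesize_beat(m)
  expect_length(b$samples, 250)
  expect_lt(abs(max(b$samples) - 1.0), 0.005)
  expect_true(which.max(b$samples) %in% c(113, 114))  # lobe center at 0.45 s
  # energy localization: zero outside [onset, onset + dur)
  tt <- (seq_len(250) - 1) / 250
  expect_true(all(b$samples[tt < 0.4 | tt >= 0.5] == 0))
})

test_that("beat synthesis is linear in amplitudes and zero for a null model", {
  seg <- data.frame(label = c("P", "R", "T"), amp = c(0.15, 1, 0.3),
                    dur = c(0.1, 0.05, 0.15), onset = c(0.1, 0.35, 0.6))
  m1 <- beat_model(seg, 1, 250)
  seg2 <- seg; seg2$amp <- 2 * seg$amp
  m2 <- beat_model(seg2, 1, 250)
  expect_equal(synthesize_beat(m2)$samples, 2 * synthesize_beat(m1)$samples)
  seg0 <- seg; seg0$amp <- 0
  expect_true(all(synthesize_beat(beat_model(seg0, 1, 250))$samples == 0))
})

test_that("invalid segment geometry is rejected", {
  expect_error(beat_model(data.frame(label = "R", amp = 1, dur = 0.2, onset = 0.9),
                          1, 250), "past the beat period")
  expect_error(beat_model(data.frame(label = c("Q", "R"), amp = c(-0.1, 1),
                                     dur = c(0.2, 0.2), onset = c(0.3, 0.4)),
                          1, 250), "overlap")
  expect_error(beat_model(data.frame(label = "R", amp = 1, dur = -0.1, onset = 0.4),
                          1, 250), "durations")
})

test_that("zero-jitter trains are strictly periodic and seeded ones reproducible", {
  m <- model_hr(60)
  x <- synthesize_ecg(m, 10, 0)
  expect_length(x, 2500)
  pk <- detect_r_peaks(x, 250)
  expect_length(pk$indices, 10)
  expect_true(all(diff(pk$indices) == 250))
  # periodic construction: dominant nonzero-lag autocorrelation at one period
  ac <- stats::acf(synthesize_ecg(m, 30, 0), lag.max = 400, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac), 250)
  # seeded determinism
  expect_identical(synthesize_ecg(m, 10, 0.02, seed = 42),
                   synthesize_ecg(m, 10, 0.02, seed = 42))
  expect_false(identical(synthesize_ecg(m, 10, 0.02, seed = 42),
                         synthesize_ecg(m, 10, 0.02, seed = 43)))
  expect_error(synthesize_ecg(m, 10, 0.25), "overlap")
})

test_that("a 75 bpm train round-trips through peak detection", {
  m <- model_hr(75)
  x <- synthesize_ecg(m, 60, 0.01, seed = 7)
  pk <- detect_r_peaks(x, 250)
  expect_true(length(pk$indices) %in% 74:75)
  expect_lt(abs(heart_rate_from_rpeaks(pk$times) - 75), 1)
})

test_that("heart rate is 60 / mean RR", {
  expect_equal(heart_rate_from_rpeaks(c(0, 0.8, 1.6, 2.4)), 75)
  expect_equal(heart_rate_from_rpeaks(c(0, 1)), 60)
  expect_equal(heart_rate_from_rpeaks(c(0, 0.9, 2.1)), 60 / 1.05)
  expect_error(heart_rate_from_rpeaks(0.5), "at least 2")
  expect_error(heart_rate_from_rpeaks(c(1, 0.5)), "increasing")
})

test_that("feature-to-model mapping carries amplitudes and the beat period", {
  f <- default_rest_features()
  m90 <- template_from_features(f, 90, 250)
  expect_equal(m90$period, 60 / 90, tolerance = 1e-12)
  expect_equal(m90$segments$amp[m90$segments$label == "R"], f$a_R)
  # degenerate P
  f0 <- ecg_features(a_P = 0, d_P = NA, t_P_R = NA, a_R = 1, d_R = 0.09,
                     t_R_T = 0.3, a_T = 0.3, d_T = 0.16)
  m0 <- template_from_features(f0, 60, 250)
  expect_false("P" %in% m0$segments$label)
  expect_error(template_from_features(f, 300, 250), "outside")
  fbad <- ecg_features(a_P = 0.1, d_P = -0.1, t_P_R = 0.18, a_R = 1, d_R = 0.09,
                       t_R_T = 0.3, a_T = 0.3, d_T = 0.16)
  expect_error(template_from_features(fbad, 60, 250), "duration")
})

test_that("features -> model -> signal -> features is a contraction", {
  f0 <- rest_features_from_signal(clean_train(60), 250)
  f1 <- rest_features_from_signal(
    synthesize_ecg(template_from_features(f0, f0$hr_bpm, 250), 30, 0), 250)
  for (nm in c("a_P", "a_R", "a_T"))
    expect_lt(abs(f1[[nm]] - f0[[nm]]) / abs(f0[[nm]]), 0.03)
  for (nm in c("d_P", "d_R", "d_T", "t_P_R", "t_R_T"))
    expect_lt(abs(f1[[nm]] - f0[[nm]]), 0.010)
})

test_that("feature files round-trip through JSON", {
  f <- default_rest_features(72)
  p <- withr::local_tempfile(fileext = ".json")
  write_features(f, p)
  g <- read_features(p)
  expect_equal(unclass(g), unclass(f), tolerance = 1e-12)
  expect_error(suppressWarnings(read_features(withr::local_tempfile(fileext = ".json"))))
})
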