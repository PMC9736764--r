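test_that("wavelet-ICA honors its contracts on clean and mismatched input", {
  clean <- clean_train(60, 30)
  expect_error(wica_denoise(clean, 250, clean[-1]), "length")
  res <- wica_denoise(clean, 250, clean, seed = 1)
  expect_s3_class(res, "ecg_denoise")
  expect_length(res$denoised, length(clean))
  expect_gt(cor(res$denoised, clean), 0.95)
})

test_that("wavelet-ICA improves a contaminated lead (median over seeds)", {
  f <- default_rest_features()
  imps <- vapply(1:5, function(sd) {
    sim <- simulate_record(model_hr(60),
                           contamination_spec(target_snr_in = -5, seed = 100 + sd), 60)
    chest <- sim$record$data[, 1]
    pk <- detect_r_peaks(chest, 250)
    ref <- reference_train(f, heart_rate_from_rpeaks(pk$times), 250,
                           length(chest), pk$times[1])
    res <- wica_denoise(chest, 250, ref, seed = sd)
    snr_report(sim$truth$clean_ecg, chest, res$denoised)$snr_imp
  }, numeric(1))
  expect_gt(median(imps), 0)
})

test_that("the redundant pipeline denoises and reports its selection", {
  sim <- sim_fixture(snr = -5, seed = 11)
  res <- rdica_denoise(sim$record, "DII", default_rest_features(), seed = 1)
  expect_s3_class(res, "rdica_denoise")
  expect_length(res$denoised, nrow(sim$record$data))
  expect_s3_class(res$report, "selection_report")
  rep <- snr_report(sim$truth$clean_ecg, sim$record$data[, 1], res$denoised)
  expect_gt(rep$snr_imp, 0)
  # residuals method returns what was removed
  expect_equal(residuals(res), res$input - res$denoised)
})

test_that("reference-based selection agrees with the ground-truth oracle", {
  agree <- 0L
  for (sd in 1:6) {
    sim <- simulate_record(model_hr(60),
                           contamination_spec(target_snr_in = -5, seed = 200 + sd), 60)
    res <- rdica_denoise(sim$record, "DII", default_rest_features(), seed = sd)
    ch <- rbind(sim$record$data[, 1], sim$record$data[, 2],
                t(sim$record$data[, 3:5]))
    mod <- fit_ica(ch, seed = sd)
    oracle <- which.max(abs(apply(mod$S, 1, cor, y = sim$truth$clean_ecg)))
    if (res$report$selected_index == oracle) agree <- agree + 1L
  }
  expect_gte(agree, 5L)
})

test_that("a record with nothing to remove passes through almost unchanged", {
  clean_rec <- simulate_record(
    model_hr(60),
    contamination_spec(target_snr_in = NA, artifact_scale = 0, seed = 3), 30)
  res <- rdica_denoise(clean_rec$record, "DII", default_rest_features(), seed = 1)
  expect_gt(cor(res$denoised, clean_rec$record$data[, 1]), 0.99)
})

test_that("missing channels are reported by site and lead", {
  sim <- sim_fixture(snr = -5, seed = 11)
  rec <- sim$record
  no_back <- ecg_record(rec$fs, rec$info[-2, ], rec$data[, -2])
  expect_error(rdica_denoise(no_back, "DII", default_rest_features()),
               "back/DII")
  no_imu <- ecg_record(rec$fs, rec$info[1:2, ], rec$data[, 1:2])
  expect_error(rdica_denoise(no_imu, "DII", default_rest_features()), "imu")
})
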