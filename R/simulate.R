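# Seeded, ground-truthed simulator for motion-contaminated redundant records.
#
# Sources are designed to satisfy the blind-source-separation assumptions the
# pipeline relies on: mutually independent, at most one near-Gaussian.
#  - cardiac source: the parametric beat train (strongly non-Gaussian);
#  - baseline wander: slow sinusoid (default 0.3 Hz) with random phase;
#  - gait artifact: a memoryless polynomial nonlinearity of the IMU
#    acceleration magnitude (walking-band energy, non-Gaussian);
#  - broadband noise: iid Laplacian draws;
#  - optional powerline sinusoid.
# Chest and back ECG channels share the cardiac source with coefficient 1 but
# mix the artifact sources with different site-specific coefficients; artifact
# power is rescaled so the chest channel hits the requested input SNR.

#' Contamination specification
#'
#' @param target_snr_in target input SNR on the chest channel, dB
#'   (`NA` disables SNR calibration).
#' @param gait_freq gait fundamental, Hz (default 1.6, normal walking pace).
#' @param baseline_wander_freq baseline wander frequency, Hz.
#' @param powerline_freq powerline frequency, Hz.
#' @param powerline_amp powerline amplitude relative to the structured artifact
#'   mix (0 disables the powerline source).
#' @param broadband_sd broadband (Laplacian) noise weight, mV per unit of
#'   structured artifact.
#' @param artifact_scale global artifact multiplier; 0 produces a clean record
#'   (only valid with `target_snr_in = NA`).
#' @param seed integer seed driving every random draw in [simulate_record()].
#' @return an object of class `contamination_spec`.
#' @export
contamination_spec <- function(target_snr_in = -5, gait_freq = 1.6,
                               baseline_wander_freq = 0.3,
                               powerline_freq = 60, powerline_amp = 0,
                               broadband_sd = 0.1, artifact_scale = 1,
                               seed = 1L) {
  if (!is.na(target_snr_in)) assert_scalar_num(target_snr_in, "target_snr_in")
  assert_scalar_num(gait_freq, "gait_freq", lower = 1e-6)
  assert_scalar_num(baseline_wander_freq, "baseline_wander_freq", lower = 1e-6)
  assert_scalar_num(broadband_sd, "broadband_sd", lower = 0)
  assert_scalar_num(artifact_scale, "artifact_scale", lower = 0)
  structure(list(target_snr_in = target_snr_in, gait_freq = gait_freq,
                 baseline_wander_freq = baseline_wander_freq,
                 powerline_freq = powerline_freq,
                 powerline_amp = powerline_amp,
                 broadband_sd = broadband_sd,
                 artifact_scale = artifact_scale, seed = as.integer(seed)),
            class = "contamination_spec")
}

#' Simulate triaxial IMU traces for walking
#'
#' The torso oscillation is modeled as a rigid-body motion: one waveform per
#' harmonic (gait fundamental and its double, with random phases drawn once
#' per record) projected onto the three axes with axis-specific random
#' amplitudes, plus a little low-pass-filtered per-axis sensor noise, on top
#' of the constant gravity reading along a random orientation (as in a real
#' accelerometer; this also makes the acceleration magnitude respond almost
#' linearly to the oscillation).
#'
#' @param duration_s,fs duration (s) and sampling rate (Hz).
#' @param gait_freq gait fundamental, Hz.
#' @param seed integer seed.
#' @return numeric matrix with columns `imu_x`, `imu_y`, `imu_z` (nominal
#'   m/s^2), `round(duration_s * fs)` rows.
#' @export
simulate_imu <- function(duration_s, fs, gait_freq = 1.6, seed = 1L) {
  assert_scalar_num(duration_s, "duration_s", lower = 1e-9)
  assert_scalar_num(fs, "fs", lower = 1e-6)
  assert_scalar_num(gait_freq, "gait_freq", lower = 1e-6)
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  lp <- signal::butter(2, min(0.99, 8 / (fs / 2)), type = "low")
  with_local_seed(seed, {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))       # sensor orientation of the vertical
    grav <- 9.81 * u
    ph <- stats::runif(2, 0, 2 * pi)
    s1 <- sin(2 * pi * gait_freq * tt + ph[1])
    s2 <- sin(2 * pi * 2 * gait_freq * tt + ph[2])
    # the gait fundamental is the vertical bounce: its loading follows the
    # gravity direction (plus a little off-axis sway); the harmonic loading
    # is unconstrained
    amp1 <- stats::runif(1, 0.7, 1.2)
    a1 <- amp1 * u + stats::rnorm(3, 0, 0.15 * amp1)
    a2 <- stats::runif(3, 0.15, 0.45)
    out <- sapply(1:3, function(i) {
      noise <- as.numeric(signal::filtfilt(lp, stats::rnorm(n, 0, 0.08)))
      grav[i] + a1[i] * s1 + a2[i] * s2 + noise
    })
    colnames(out) <- c("imu_x", "imu_y", "imu_z")
    out
  })
}

# standardized Laplacian draws (difference of unit exponentials has variance 2)
rlaplace_std <- function(n) (stats::rexp(n) - stats::rexp(n)) / sqrt(2)

#' Simulate a contaminated redundant record with ground truth
#'
#' Builds the linear mixing of a clean cardiac beat train with baseline wander,
#' a gait-correlated artifact derived from the simulated IMU magnitude, and
#' broadband Laplacian noise; forms chest and back ECG channels (shared cardiac
#' source, site-specific artifact coefficients) plus the three IMU channels.
#' Artifact power is rescaled so the chest channel's input SNR matches
#' `spec$target_snr_in` (within floating point).
#'
#' @param model a [beat_model()] for the cardiac source.
#' @param spec a [contamination_spec()].
#' @param duration_s record duration, seconds.
#' @param lead lead name used in the channel labels (default `"DII"`).
#' @param rr_jitter_sd RR variability of the cardiac source, seconds.
#' @return an object of class `sim_record`: list with `record`
#'   (an [ecg_record()]) and `truth` (clean source, artifact sources, mixing
#'   matrix, achieved per-channel input SNR).
#' @export
simulate_record <- function(model, spec, duration_s, lead = "DII",
                            rr_jitter_sd = 0.01) {
  stopifnot(inherits(model, "beat_model"), inherits(spec, "contamination_spec"))
  fs <- model$fs
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  seed <- spec$seed

  clean <- synthesize_ecg(model, duration_s, rr_jitter_sd, seed = seed)
  imu <- simulate_imu(duration_s, fs, spec$gait_freq, seed = seed + 1000L)

  srcs <- with_local_seed(seed + 2000L, {
    bw <- sin(2 * pi * spec$baseline_wander_freq * tt + stats::runif(1, 0, 2 * pi))
    # electrode-motion artifact: memoryless nonlinearity (mild quadratic and
    # cubic distortion) of the acceleration magnitude, plus independent noise
    mag <- zscore(sqrt(rowSums(imu^2)))
    gait <- zscore(mag + 0.15 * mag^2 + 0.05 * mag^3) + 0.1 * rlaplace_std(n)
    gait <- zscore(gait)
    bb <- rlaplace_std(n)
    s <- rbind(baseline = zscore(bw), gait = gait, broadband = bb)
    if (spec$powerline_amp > 0) {
      pl <- sin(2 * pi * spec$powerline_freq * tt + stats::runif(1, 0, 2 * pi))
      s <- rbind(s, powerline = zscore(pl) * spec$powerline_amp)
    }
    s
  })

  # site-specific unit coefficients for (baseline, gait, broadband[, powerline]);
  # chest and back see clearly different artifact mixtures (redundancy premise)
  co_chest <- c(0.25, 0.55, 0.5 * spec$broadband_sd)
  co_back <- c(0.70, 0.15, 0.4 * spec$broadband_sd)
  if (spec$powerline_amp > 0) {
    co_chest <- c(co_chest, 1)
    co_back <- c(co_back, 0.8)
  }

  if (spec$artifact_scale == 0) {
    if (!is.na(spec$target_snr_in) && is.finite(spec$target_snr_in))
      stopf("target SNR %g dB is unreachable with zero-amplitude artifacts",
            spec$target_snr_in)
    k <- 0
  } else {
    noise_unit <- as.numeric(co_chest %*% srcs)
    if (!is.na(spec$target_snr_in) && is.finite(spec$target_snr_in)) {
      if (all(noise_unit == 0))
        stopf("target SNR %g dB is unreachable with zero-amplitude artifacts",
              spec$target_snr_in)
      k <- sqrt(mean(clean^2) / mean(noise_unit^2) *
                  10^(-spec$target_snr_in / 10))
    } else k <- spec$artifact_scale
  }

  A <- rbind(chest = c(1, k * co_chest), back = c(1, k * co_back))
  colnames(A) <- c("ecg", rownames(srcs))
  sources <- rbind(ecg = clean, srcs)
  ecg_ch <- A %*% sources

  snr_of <- function(x) {
    err <- x - clean
    if (all(err == 0)) Inf else 10 * log10(sum(clean^2) / sum(err^2))
  }
  achieved <- c(chest = snr_of(ecg_ch["chest", ]), back = snr_of(ecg_ch["back", ]))

  labels <- c(paste0("chest_", lead), paste0("back_", lead),
              "imu_x", "imu_y", "imu_z")
  info <- data.frame(
    label = labels,
    site = c("chest", "back", "none", "none", "none"),
    kind = c("ecg", "ecg", "imu_x", "imu_y", "imu_z"),
    units = c("mV", "mV", "m/s2", "m/s2", "m/s2"))
  data <- cbind(ecg_ch["chest", ], ecg_ch["back", ], imu)
  record <- ecg_record(fs, info, data,
                       meta = list(generator = "rdica-simulator", seed = seed,
                                   target_snr_in = spec$target_snr_in,
                                   gait_freq = spec$gait_freq,
                                   hr_bpm = 60 / model$period,
                                   rr_jitter_sd = rr_jitter_sd))
  truth <- structure(list(clean_ecg = clean, artifact_sources = srcs,
                          mixing_matrix = A, achieved_snr_in = achieved),
                     class = "sim_ground_truth")
  structure(list(record = record, truth = truth), class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat("Simulated contaminated record\n")
  print(x$record)
  cat(sprintf("achieved SNR_in: chest %.3f dB, back %.3f dB\n",
              x$truth$achieved_snr_in["chest"], x$truth$achieved_snr_in["back"]))
  invisible(x)
}

#' Write / read a ground-truth sidecar file
#'
#' Plain-text CSV: `#`-prefixed header lines carry the mixing matrix and
#' achieved SNR (as JSON); data columns are the clean cardiac source and the
#' artifact sources.
#'
#' @param truth a `sim_ground_truth` (from [simulate_record()]).
#' @param path file path.
#' @return `read_ground_truth` returns a `sim_ground_truth`;
#'   `write_ground_truth` returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_ground_truth"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mixing_matrix=%s",
                     jsonlite::toJSON(truth$mixing_matrix, digits = NA)), con)
  writeLines(sprintf("# mixing_rows=%s",
                     paste(rownames(truth$mixing_matrix), collapse = ";")), con)
  writeLines(sprintf("# mixing_cols=%s",
                     paste(colnames(truth$mixing_matrix), collapse = ";")), con)
  writeLines(sprintf("# achieved_snr_in=%s",
                     jsonlite::toJSON(truth$achieved_snr_in, digits = NA)), con)
  m <- cbind(clean_ecg = truth$clean_ecg, t(truth$artifact_sources))
  writeLines(paste(colnames(m), collapse = ","), con)
  utils::write.table(format(m, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  get <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "="), lines, value = TRUE)[1]
    sub(paste0("^#\\s*", key, "="), "", ln)
  }
  A <- jsonlite::fromJSON(get("mixing_matrix"))
  rownames(A) <- strsplit(get("mixing_rows"), ";")[[1]]
  colnames(A) <- strsplit(get("mixing_cols"), ";")[[1]]
  snr <- unlist(jsonlite::fromJSON(get("achieved_snr_in")))
  names(snr) <- rownames(A)
  body <- lines[!hdr]
  cols <- strsplit(body[1], ",")[[1]]
  vals <- matrix(as.numeric(unlist(strsplit(body[-1], ","))),
                 ncol = length(cols), byrow = TRUE)
  colnames(vals) <- cols
  structure(list(clean_ecg = vals[, "clean_ecg"],
                 artifact_sources = t(vals[, setdiff(cols, "clean_ecg"), drop = FALSE]),
                 mixing_matrix = A, achieved_snr_in = snr),
            class = "sim_ground_truth")
}
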