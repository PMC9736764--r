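# The three denoisers. Each returns an `ecg_denoise` object in the
# chest-channel amplitude frame, so the ICA sign/scale indeterminacy never
# reaches the user.

# WICA component-retention rule (automated stand-in for visual inspection):
# keep sources whose |r| against the reference is at least
# max(WICA_KEEP_REL * max r, WICA_KEEP_ABS).
WICA_KEEP_REL <- 0.5
WICA_KEEP_ABS <- 0.2

new_ecg_denoise <- function(denoised, input, fs, method, report = NULL,
                            params = list()) {
  structure(list(denoised = denoised, input = input, fs = fs, method = method,
                 report = report, params = params),
            class = c(paste0(method, "_denoise"), "ecg_denoise"))
}

#' @export
print.ecg_denoise <- function(x, ...) {
  cat(sprintf("ECG denoising result: method '%s', %d samples at %g Hz\n",
              x$method, length(x$denoised), x$fs))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' @export
summary.ecg_denoise <- function(object, ...) {
  res <- object$input - object$denoised
  cat(sprintf("Method: %s\n", object$method))
  cat(sprintf("Samples: %d at %g Hz (%.1f s)\n", length(object$denoised),
              object$fs, length(object$denoised) / object$fs))
  cat(sprintf("Removed component RMS: %.4f mV (input RMS %.4f mV)\n",
              rms(res - mean(res)), rms(object$input - mean(object$input))))
  if (!is.null(object$report)) print(object$report)
  invisible(object)
}

#' @export
residuals.ecg_denoise <- function(object, ...) object$input - object$denoised

#' @export
plot.ecg_denoise <- function(x, max_s = 10, ...) {
  n <- min(length(x$input), round(max_s * x$fs))
  tt <- (seq_len(n) - 1) / x$fs
  graphics::plot(tt, x$input[seq_len(n)], type = "l", col = "grey60",
                 xlab = "s", ylab = "mV",
                 main = sprintf("denoising (%s)", x$method), ...)
  graphics::lines(tt, x$denoised[seq_len(n)], col = "black")
  graphics::legend("topright", c("input", "denoised"),
                   col = c("grey60", "black"), lty = 1, bty = "n")
  invisible(x)
}

#' Wavelet-shrinkage denoiser (single channel)
#'
#' Thin front-end over [wavelet_shrinkage()] returning the common result class.
#'
#' @param x contaminated signal, mV.
#' @param fs sampling rate, Hz.
#' @param wspec a [wavelet_spec()].
#' @return an `ecg_denoise` object.
#' @export
ws_denoise <- function(x, fs, wspec = wavelet_spec()) {
  new_ecg_denoise(wavelet_shrinkage(x, wspec), x, fs, "ws",
                  params = list(wspec = wspec))
}

#' Wavelet-ICA denoiser (single channel)
#'
#' Stationary wavelet decomposition of one lead yields equal-length coefficient
#' sequences; these form the multichannel input of [fit_ica()]. Sources whose
#' |Pearson r| against the reference beat train passes the retention rule are
#' kept, back-reconstructed into the coefficient channels, and inverse
#' transformed.
#'
#' @param x contaminated signal, mV.
#' @param fs sampling rate, Hz.
#' @param reference reference beat train, same length as `x`.
#' @param wspec a [wavelet_spec()].
#' @param seed integer seed for the ICA initialization.
#' @return an `ecg_denoise` object; the report records the per-source
#'   correlations and the kept set.
#' @export
wica_denoise <- function(x, fs, reference, wspec = wavelet_spec(), seed = 1L) {
  if (length(reference) != length(x))
    stopf("reference length (%d) must equal signal length (%d)",
          length(reference), length(x))
  coeffs <- swt_decompose(x, wspec$family, wspec$levels)
  model <- fit_ica(t(coeffs), seed = seed)
  # score each source by its reconstructed contribution to the lead: the
  # inverse transform restores the analysis filters' phase, so a zero-lag
  # correlation against the reference is meaningful
  n_src <- nrow(model$S)
  r <- vapply(seq_len(n_src), function(i) {
    S0 <- matrix(0, n_src, ncol(model$S))
    S0[i, ] <- model$S[i, ]
    contrib <- swt_reconstruct(t(model$A %*% S0), wspec$family)
    if (stats::sd(contrib) == 0) 0 else abs(stats::cor(contrib, reference))
  }, numeric(1))
  keep <- which(r >= max(WICA_KEEP_REL * max(r), WICA_KEEP_ABS))
  if (!length(keep)) keep <- which.max(r)
  S0 <- model$S
  S0[setdiff(seq_len(n_src), keep), ] <- 0
  rec <- model$A %*% S0 + model$center
  denoised <- swt_reconstruct(t(rec), wspec$family)
  sel <- structure(list(correlations = r, selected_index = which.max(r),
                        reference_hr = NA_real_, low_confidence = !any(r > 0),
                        kept = keep),
                   class = "selection_report")
  new_ecg_denoise(denoised, x, fs, "wica", report = sel,
                  params = list(wspec = wspec, seed = seed))
}

#' Redundant-denoising ICA (Rd-ICA)
#'
#' The full pipeline on a redundant record: (1) measure the heart rate on the
#' contaminated chest lead; (2) synthesize a reference beat train from the
#' resting features at that heart rate (zero jitter), aligned to the first
#' detected R peak; (3) assemble the 5-channel set (chest ECG, back ECG, three
#' IMU axes); (4) separate sources with [fit_ica()]; (5) select the source
#' best correlated with the reference; (6) back-reconstruct it onto the chest
#' channel; (7) polish with [wavelet_shrinkage()].
#'
#' If heart-rate estimation fails on the contaminated lead, the resting heart
#' rate is used with a warning. If the chest and back leads are numerically
#' identical (no artifact to separate), the ICA stage is skipped and the chest
#' lead is polished directly.
#'
#' @param record an [ecg_record()] with the lead at both chest and back sites
#'   plus the three IMU channels.
#' @param lead lead name, e.g. `"DII"`.
#' @param rest_features an [ecg_features()] measured at rest (see
#'   [rest_features_from_signal()]).
#' @param wspec a [wavelet_spec()] for the final polish.
#' @param seed integer seed for the ICA initialization.
#' @return an `ecg_denoise` object whose `report` is the
#'   [select_component()] selection report.
#' @export
rdica_denoise <- function(record, lead = "DII", rest_features,
                          wspec = wavelet_spec(), seed = 1L) {
  stopifnot(inherits(record, "ecg_record"), inherits(rest_features, "ecg_features"))
  fs <- record$fs
  chest_lab <- find_ecg_channel(record, lead, "chest")
  back_lab <- find_ecg_channel(record, lead, "back")
  imu_lab <- find_imu_channels(record)
  chest <- record_channel(record, chest_lab)
  back <- record_channel(record, back_lab)

  hr <- NULL; t_first_r <- NULL
  pk <- tryCatch(detect_r_peaks(chest, fs), error = function(e) NULL)
  if (!is.null(pk)) {
    est <- heart_rate_from_rpeaks(pk$times)
    if (est > 20 && est < 250) { hr <- est; t_first_r <- pk$times[1] }
  }
  if (is.null(hr)) {
    if (is.na(rest_features$hr_bpm))
      stopf("heart-rate estimation failed and rest features carry no hr_bpm")
    warnf("heart-rate estimation failed on the contaminated lead; using resting HR %.1f bpm",
          rest_features$hr_bpm)
    hr <- rest_features$hr_bpm
    t_first_r <- NULL
  }

  ref <- reference_train(rest_features, hr, fs, length(chest), t_first_r)

  if (stats::cor(chest, back) > 1 - 1e-9) {
    # redundant leads agree exactly: no independent artifact content to separate
    denoised <- wavelet_shrinkage(chest, wspec)
    sel <- structure(list(correlations = stats::cor(zscore(chest), zscore(ref)),
                          selected_index = 1L, reference_hr = hr,
                          low_confidence = FALSE, ica_skipped = TRUE),
                     class = "selection_report")
    return(new_ecg_denoise(denoised, chest, fs, "rdica", report = sel,
                           params = list(wspec = wspec, seed = seed, lead = lead)))
  }

  channels <- rbind(chest, back,
                    record_channel(record, imu_lab[1]),
                    record_channel(record, imu_lab[2]),
                    record_channel(record, imu_lab[3]))
  model <- fit_ica(channels, seed = seed)
  sel <- select_component(model, ref, reference_hr = hr)
  recon <- back_reconstruct(model, keep = sel$selected_index, channel = 1L) +
    mean(chest)
  denoised <- wavelet_shrinkage(recon, wspec)
  new_ecg_denoise(denoised, chest, fs, "rdica", report = sel,
                  params = list(wspec = wspec, seed = seed, lead = lead))
}

#' Reference beat train from resting features
#'
#' Synthesizes a zero-jitter beat train from the resting waveform features at
#' the given heart rate, optionally shifted so an R peak falls at
#' `t_first_r` seconds (alignment to the first detected R of the signal under
#' repair).
#'
#' @param rest_features an [ecg_features()].
#' @param hr heart rate, bpm.
#' @param fs sampling rate, Hz.
#' @param n output length, samples.
#' @param t_first_r optional time (s) of the first R peak to align to.
#' @return numeric vector of length `n`.
#' @export
reference_train <- function(rest_features, hr, fs, n, t_first_r = NULL) {
  model <- template_from_features(rest_features, hr, fs)
  period <- model$period
  n_beat <- round(period * fs)
  full <- synthesize_ecg(model, (n + 2 * n_beat) / fs, rr_jitter_sd = 0)
  shift <- 0L
  if (!is.null(t_first_r)) {
    # model R centers sit at (R_CENTER_FRAC + k) * period
    delta <- (R_CENTER_FRAC * period - t_first_r) %% period
    shift <- round(delta * fs)
  }
  full[(shift + 1):(shift + n)]
}
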