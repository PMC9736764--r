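# Ensemble-average ECG: R-peak detection, beat epoching around the R fiducial,
# mean +/- SD beat, and the 8-feature waveform characterization
# (a_P, d_P, t_P-R, a_R, d_R, t_R-T, a_T, d_T).

# Named configurable constants for the feature-extraction conventions.
EA_WINDOW_FRACS <- c(pre = 0.4, post = 0.6)    # beat window split around R, x RRmed
EA_BASELINE_WIN <- c(-0.10, -0.05)             # PR isoelectric window, s from R
EA_P_WIN <- c(-0.30, -0.10)                    # P search window, s from R
EA_QRS_WIN <- c(-0.05, 0.05)                   # QRS search window, s from R
EA_T_WIN <- c(0.15, 0.45)                      # T search window, s from R
EA_DUR_THRESH <- 0.05                          # duration threshold, x peak deviation
EA_RR_SCALE_REF <- 0.6                         # windows shrink when RR < this, s
RPEAK_REFRACTORY <- 0.25                       # s
RPEAK_BAND <- c(5, 15)                         # QRS-emphasis band, Hz

#' Detect R peaks
#'
#' Band-pass (5-15 Hz) energy emphasis, adaptive threshold, 0.25 s refractory;
#' each returned peak is then refined to the raw-signal extremum within
#' +/- 50 ms of the detection. Polarity (upright or inverted R) is detected
#' automatically by default.
#'
#' @param x numeric signal, mV; at least 2 s of samples.
#' @param fs sampling rate, Hz.
#' @param polarity `"auto"`, `"up"` or `"down"`.
#' @return an object of class `rpeak_list`: `indices` (1-based sample
#'   positions), `times` (seconds), `fs`, `polarity`.
#' @export
detect_r_peaks <- function(x, fs, polarity = c("auto", "up", "down")) {
  polarity <- match.arg(polarity)
  assert_scalar_num(fs, "fs", lower = 1e-6)
  if (length(x) < 2 * fs) stopf("need at least 2 s of signal (%d samples)", 2 * fs)
  if (stats::sd(x) == 0) stopf("no peaks: signal is flat")
  xc <- x - stats::median(x)

  bf <- signal::butter(3, pmin(0.99, RPEAK_BAND / (fs / 2)), type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, xc))
  # derivative emphasis: QRS slopes dominate slower movement-band content
  dv <- as.numeric(stats::filter(bp, c(1, 2, 0, -2, -1) / 8, sides = 2))
  dv[is.na(dv)] <- 0
  en <- dv^2
  w <- max(3L, round(0.15 * fs))
  sm <- as.numeric(stats::filter(en, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- 0

  n <- length(sm)
  is_max <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] & sm[2:(n - 1)] >= sm[3:n], FALSE)
  cand <- which(is_max & sm > 0)
  if (!length(cand)) stopf("no peaks detected")
  # adaptive threshold: anchored on the energies of the beats one would expect
  # at a minimal physiological rate (>= 40 bpm)
  m <- max(2L, ceiling(length(x) / fs / 1.5))
  top <- sort(sm[cand], decreasing = TRUE)[seq_len(min(m, length(cand)))]
  thr <- 0.5 * stats::median(top)

  refr <- round(RPEAK_REFRACTORY * fs)
  keep <- integer(0)
  for (i in cand[sm[cand] >= thr]) {
    if (!length(keep) || i - keep[length(keep)] >= refr) keep <- c(keep, i)
    else if (sm[i] > sm[keep[length(keep)]]) keep[length(keep)] <- i
  }
  if (length(keep) >= 3) {
    # search-back: recover missed beats inside long RR gaps at half threshold
    repeat {
      rr <- diff(keep)
      med <- stats::median(rr)
      added <- FALSE
      for (g in which(rr > 1.6 * med)) {
        lo <- keep[g] + refr; hi <- keep[g + 1] - refr
        if (lo >= hi) next
        cc <- cand[cand >= lo & cand <= hi]
        cc <- cc[sm[cc] >= 0.5 * thr]
        if (length(cc)) {
          keep <- sort(c(keep, cc[which.max(sm[cc])]))
          added <- TRUE
          break
        }
      }
      if (!added) break
    }
    # drop the weaker of any pair of detections closer than 0.7 * median RR
    repeat {
      if (length(keep) < 3) break
      rr <- diff(keep)
      bad <- which(rr < 0.7 * stats::median(rr))
      if (!length(bad)) break
      b <- bad[1]
      keep <- keep[-(if (sm[keep[b]] < sm[keep[b + 1]]) b else b + 1)]
    }
  }
  if (length(keep) < 2) stopf("no peaks: fewer than 2 beats detected")

  # refine on the raw signal within +/- 50 ms
  hw <- as.integer(round(0.05 * fs))
  win_ext <- function(i, f) {
    lo <- max(1L, as.integer(i) - hw); hi <- min(length(xc), as.integer(i) + hw)
    lo - 1L + as.integer(f(xc[lo:hi]))
  }
  if (polarity == "auto") {
    up_mag <- mean(vapply(keep, function(i) max(xc[max(1, i - hw):min(n, i + hw)]), 0))
    dn_mag <- mean(vapply(keep, function(i) -min(xc[max(1, i - hw):min(n, i + hw)]), 0))
    polarity <- if (dn_mag > up_mag) "down" else "up"
  }
  f <- if (polarity == "up") which.max else which.min
  idx <- sort(unique(vapply(keep, win_ext, integer(1), f = f)))
  # refinement can merge neighbours; re-apply the refractory
  idx <- idx[c(TRUE, diff(idx) >= refr)]
  if (length(idx) < 2) stopf("no peaks: fewer than 2 beats detected")
  structure(list(indices = idx, times = (idx - 1) / fs, fs = fs,
                 polarity = polarity), class = "rpeak_list")
}

#' @export
print.rpeak_list <- function(x, ...) {
  cat(sprintf("%d R peaks (%s polarity), HR %.1f bpm\n", length(x$indices),
              x$polarity, heart_rate_from_rpeaks(x$times)))
  invisible(x)
}

#' Ensemble-average ECG
#'
#' Beats are epoched on `[R - f_pre * RRmed, R + f_post * RRmed)` (defaults
#' 0.4 / 0.6 of the median RR), aligned at the R fiducial, and averaged; the
#' per-sample SD is returned alongside. Beats whose window exceeds the signal
#' bounds are discarded.
#'
#' @param x numeric signal, mV.
#' @param rpeaks an `rpeak_list` from [detect_r_peaks()].
#' @param window_fracs length-2 vector `c(pre, post)` of RRmed fractions.
#' @return an object of class `ecg_ensemble`: `mean_beat`, `sd_beat`,
#'   `n_beats`, `fiducial_index` (1-based offset of R in the window), `fs`,
#'   `rr_mean`, `rr_sd` (seconds).
#' @export
ensemble_average <- function(x, rpeaks, window_fracs = EA_WINDOW_FRACS) {
  stopifnot(inherits(rpeaks, "rpeak_list"), length(window_fracs) == 2)
  idx <- rpeaks$indices
  if (length(idx) < 2) stopf("need at least 2 beats")
  rr <- diff(idx)
  rrmed <- stats::median(rr)
  n_pre <- round(window_fracs[[1]] * rrmed)
  n_post <- round(window_fracs[[2]] * rrmed)
  L <- n_pre + n_post
  usable <- idx[idx - n_pre >= 1 & idx + n_post - 1 <= length(x)]
  if (length(usable) < 2) stopf("fewer than 2 usable beats after edge discard")
  beats <- vapply(usable, function(i) x[(i - n_pre):(i + n_post - 1)],
                  numeric(L))
  m <- rowMeans(beats)
  s <- apply(beats, 1, stats::sd)
  structure(list(mean_beat = m, sd_beat = s, n_beats = length(usable),
                 fiducial_index = n_pre + 1L, fs = rpeaks$fs,
                 rr_mean = mean(rr) / rpeaks$fs,
                 rr_sd = stats::sd(rr) / rpeaks$fs),
            class = "ecg_ensemble")
}

#' @export
print.ecg_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble-average ECG: %d beats, window %d samples, RR %.3f (SD %.3f) s\n",
              x$n_beats, length(x$mean_beat), x$rr_mean, x$rr_sd))
  invisible(x)
}

#' @export
plot.ecg_ensemble <- function(x, ...) {
  tt <- (seq_along(x$mean_beat) - x$fiducial_index) / x$fs
  graphics::plot(tt, x$mean_beat, type = "l", xlab = "time from R (s)",
                 ylab = "mV", ...)
  graphics::lines(tt, x$mean_beat + x$sd_beat, lty = 2)
  graphics::lines(tt, x$mean_beat - x$sd_beat, lty = 2)
  invisible(x)
}

# clamp a [lo, hi] second-window (relative to R) to valid 1-based indices
ea_window_idx <- function(fi, fs, win, n, scale = 1) {
  lo <- max(1L, fi + round(win[1] * scale * fs))
  hi <- min(n, fi + round(win[2] * scale * fs))
  if (lo > hi) integer(0) else lo:hi
}

#' Extract the 8 waveform features from an ensemble-average beat
#'
#' The baseline is the mean of the PR isoelectric window (0.10 to 0.05 s
#' before R). Amplitudes are the signed extremum deviations from baseline in
#' per-segment search windows (P: 0.30-0.10 s before R; QRS: +/- 0.05 s;
#' T: 0.15-0.45 s after R; all shrunk proportionally when RR < 0.6 s).
#' Durations are the extent over which the deviation exceeds 5% of the
#' segment's peak deviation. `t_P_R` / `t_R_T` are extremum-to-R times.
#' A P or T extremum below twice the baseline-window SD is reported as
#' amplitude 0 with absent duration.
#'
#' @param ens an `ecg_ensemble` from [ensemble_average()].
#' @return an [ecg_features()] object.
#' @export
extract_features <- function(ens) {
  stopifnot(inherits(ens, "ecg_ensemble"))
  beat <- ens$mean_beat
  fs <- ens$fs
  fi <- ens$fiducial_index
  n <- length(beat)
  scale <- min(1, ens$rr_mean / EA_RR_SCALE_REF)

  bidx <- ea_window_idx(fi, fs, EA_BASELINE_WIN, n, scale)
  if (!length(bidx)) stopf("beat window too short to locate the PR baseline")
  baseline <- mean(beat[bidx])
  bsd <- stats::sd(beat[bidx])
  dev <- beat - baseline

  seg_measure <- function(win, guard = FALSE) {
    widx <- ea_window_idx(fi, fs, win, n, scale)
    if (!length(widx)) return(list(a = 0, d = NA_real_, i = NA_integer_))
    k <- widx[which.max(abs(dev[widx]))]
    a <- dev[k]
    if (guard && abs(a) < 2 * bsd)
      return(list(a = 0, d = NA_real_, i = NA_integer_))
    exceed <- widx[abs(dev[widx]) >= EA_DUR_THRESH * abs(a)]
    d <- (max(exceed) - min(exceed) + 1) / fs
    list(a = a, d = d, i = k)
  }

  qrs <- seg_measure(EA_QRS_WIN)
  if (is.na(qrs$i)) stopf("no identifiable R deflection at the fiducial")
  p <- seg_measure(EA_P_WIN, guard = TRUE)
  tw <- seg_measure(EA_T_WIN, guard = TRUE)

  ecg_features(
    a_P = p$a, d_P = p$d,
    t_P_R = if (is.na(p$i)) NA_real_ else (qrs$i - p$i) / fs,
    a_R = qrs$a, d_R = qrs$d,
    t_R_T = if (is.na(tw$i)) NA_real_ else (tw$i - qrs$i) / fs,
    a_T = tw$a, d_T = tw$d,
    hr_bpm = 60 / ens$rr_mean)
}

#' Rest features from a clean resting record channel
#'
#' Convenience wrapper: detect R peaks, ensemble-average, extract features.
#'
#' @param x numeric signal, mV.
#' @param fs sampling rate, Hz.
#' @return an [ecg_features()] object (with `hr_bpm` set).
#' @export
rest_features_from_signal <- function(x, fs) {
  extract_features(ensemble_average(x, detect_r_peaks(x, fs)))
}
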