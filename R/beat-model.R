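# Parametric single-beat model: each ECG segment (P, Q, R, S, T, U) is a
# raised-cosine lobe a * (1 - cos(2*pi*u))/2, u = (t - onset)/dur, compactly
# supported on [onset, onset + dur). Smooth, peak equals the amplitude at the
# lobe center, and zero elsewhere, so segments are locally identifiable.

# Fraction of a lobe's duration over which it exceeds 5% of its peak; used to
# convert between threshold-crossing widths (measured features) and lobe
# durations (model coefficients).
LOBE_WIDTH_5PCT <- 1 - acos(0.9) / pi

# R-lobe center as a fraction of the beat period.
R_CENTER_FRAC <- 0.4

# Fixed QRS geometry: Q and S lobe centers sit one R-lobe duration before and
# after the R center, with half its duration and amplitudes -0.1/-0.2 of a_R.
# Under the 5% width rule the measured QRS extent is then 55/24 of the R-lobe
# duration, which keeps the 8-feature parameterization invertible.
QRS_EXTENT_PER_RLOBE <- 55 / 24
Q_AMP_FRAC <- -0.1
S_AMP_FRAC <- -0.2

#' Construct a parametric beat model
#'
#' A beat model holds the per-segment coefficients (amplitude, duration, onset,
#' baseline offset) of a raised-cosine segment expansion of one cardiac cycle,
#' together with the beat period and sampling rate.
#'
#' @param segments data frame with columns `label` (one of P,Q,R,S,T,U),
#'   `amp` (mV), `dur` (s, > 0), `onset` (s, in `[0, period)`), and optionally
#'   `base` (mV baseline offset, default 0).
#' @param period beat period in seconds (60 / heart rate).
#' @param fs sampling rate in Hz.
#' @return an object of class `beat_model`.
#' @export
beat_model <- function(segments, period, fs) {
  assert_scalar_num(period, "period", lower = 1e-6)
  assert_scalar_num(fs, "fs", lower = 1e-6)
  stopifnot(is.data.frame(segments))
  need <- c("label", "amp", "dur", "onset")
  if (!all(need %in% names(segments)))
    stopf("segments must have columns %s", paste(need, collapse = ", "))
  if (is.null(segments$base)) segments$base <- 0
  if (!all(segments$label %in% c("P", "Q", "R", "S", "T", "U")))
    stopf("segment labels must be among P,Q,R,S,T,U")
  if (any(segments$dur <= 0)) stopf("segment durations must be > 0")
  if (any(segments$onset < 0)) stopf("segment onsets must be >= 0")
  if (any(segments$onset + segments$dur > period + 1e-9))
    stopf("segment extends past the beat period (onset + dur > period)")
  segments <- segments[order(segments$onset), , drop = FALSE]
  if (nrow(segments) > 1) {
    ends <- segments$onset + segments$dur
    if (any(segments$onset[-1] < ends[-nrow(segments)] - 1e-12))
      stopf("segments overlap in time")
  }
  structure(list(segments = segments, period = period, fs = fs),
            class = "beat_model")
}

#' @export
print.beat_model <- function(x, ...) {
  cat(sprintf("Beat model: %d segments, period %.4f s (HR %.1f bpm), fs %g Hz\n",
              nrow(x$segments), x$period, 60 / x$period, x$fs))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

# Evaluate the segment expansion at arbitrary times (seconds from beat onset).
eval_segments <- function(segments, tvec) {
  out <- numeric(length(tvec))
  for (i in seq_len(nrow(segments))) {
    u <- (tvec - segments$onset[i]) / segments$dur[i]
    inside <- u >= 0 & u < 1
    out[inside] <- out[inside] +
      segments$amp[i] * (1 - cos(2 * pi * u[inside])) / 2 + segments$base[i]
  }
  out
}

#' Synthesize one beat from a beat model
#'
#' Samples the segment expansion on `[0, period)` at the model's sampling rate.
#'
#' @param model a [beat_model()].
#' @return an object of class `beat_template`: list with `samples` (mV) and
#'   `fs` (Hz); length `round(period * fs)`.
#' @export
synthesize_beat <- function(model) {
  stopifnot(inherits(model, "beat_model"))
  n <- round(model$period * model$fs)
  tvec <- (seq_len(n) - 1) / model$fs
  structure(list(samples = eval_segments(model$segments, tvec), fs = model$fs),
            class = "beat_template")
}

#' @export
print.beat_template <- function(x, ...) {
  cat(sprintf("Beat template: %d samples at %g Hz (%.3f s), range [%.3f, %.3f] mV\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Synthesize a continuous ECG signal as a train of model beats
#'
#' Beats are concatenated with RR intervals drawn as `period + N(0, rr_jitter_sd)`,
#' truncated at +/- 0.2 * period so beats cannot collide. Segment onsets stay
#' fixed relative to each beat's start, so mild RR variability stretches or
#' shortens the diastolic baseline, as in sinus-rhythm recordings.
#'
#' @param model a [beat_model()].
#' @param duration_s signal duration in seconds.
#' @param rr_jitter_sd standard deviation of the RR jitter, seconds
#'   (must be < 0.2 * period).
#' @param seed integer seed; the draw is fully reproducible and the caller's
#'   RNG state is untouched.
#' @return numeric vector of `round(duration_s * fs)` samples (mV).
#' @export
synthesize_ecg <- function(model, duration_s, rr_jitter_sd = 0, seed = 1L) {
  stopifnot(inherits(model, "beat_model"))
  assert_scalar_num(duration_s, "duration_s", lower = 1e-9)
  assert_scalar_num(rr_jitter_sd, "rr_jitter_sd", lower = 0)
  if (rr_jitter_sd >= 0.2 * model$period)
    stopf("rr_jitter_sd = %g s is >= 0.2 * period (%g s): beats would overlap",
          rr_jitter_sd, 0.2 * model$period)
  fs <- model$fs
  n_total <- round(duration_s * fs)
  lim <- 0.2 * model$period
  with_local_seed(seed, {
    out <- numeric(n_total)
    t_cum <- 0
    i0 <- 0L  # samples emitted so far
    while (i0 < n_total) {
      rr <- model$period
      if (rr_jitter_sd > 0) {
        j <- stats::rnorm(1, 0, rr_jitter_sd)
        rr <- model$period + max(-lim, min(lim, j))
      }
      i1 <- min(n_total, round((t_cum + rr) * fs))
      n_i <- i1 - i0
      if (n_i > 0) {
        tvec <- (seq_len(n_i) - 1) / fs
        out[(i0 + 1):i1] <- eval_segments(model$segments, tvec)
      }
      t_cum <- t_cum + rr
      i0 <- max(i1, i0 + 1L)
    }
    out
  })
}

#' Default resting ensemble-average features
#'
#' A normal adult resting beat: upright P (0.15 mV, 90 ms), dominant R
#' (1.0 mV, 90 ms QRS), upright T (0.3 mV, 160 ms), PR and RT intervals
#' (extremum-to-R) of 180 and 300 ms, at 60 bpm. Q and S deflections are folded
#' into the QRS complex with fixed amplitude fractions of R.
#'
#' @param hr_bpm resting heart rate, bpm.
#' @return an `ecg_features` object (see [template_from_features()]).
#' @export
default_rest_features <- function(hr_bpm = 60) {
  ecg_features(a_P = 0.15, d_P = 0.09, t_P_R = 0.18,
               a_R = 1.0, d_R = 0.09, t_R_T = 0.30,
               a_T = 0.3, d_T = 0.16, hr_bpm = hr_bpm)
}

#' Create an 8-feature waveform description
#'
#' The feature vector used throughout the package, in fixed order:
#' `a_P, d_P, t_P_R, a_R, d_R, t_R_T, a_T, d_T` — amplitudes in mV, durations
#' and intervals in seconds. `t_P_R` and `t_R_T` are the (positive) times from
#' the P / T extremum to the R peak.
#'
#' @param a_P,d_P,t_P_R,a_R,d_R,t_R_T,a_T,d_T the eight features.
#' @param hr_bpm optional heart rate the features were measured at.
#' @return an object of class `ecg_features`.
#' @export
ecg_features <- function(a_P, d_P, t_P_R, a_R, d_R, t_R_T, a_T, d_T,
                         hr_bpm = NA_real_) {
  x <- list(a_P = a_P, d_P = d_P, t_P_R = t_P_R, a_R = a_R, d_R = d_R,
            t_R_T = t_R_T, a_T = a_T, d_T = d_T, hr_bpm = hr_bpm)
  num <- unlist(x[FEATURE_NAMES])
  if (any(!is.na(num) & !is.finite(num))) stopf("features must be finite")
  structure(x, class = "ecg_features")
}

FEATURE_NAMES <- c("a_P", "d_P", "t_P_R", "a_R", "d_R", "t_R_T", "a_T", "d_T")

#' @export
print.ecg_features <- function(x, ...) {
  cat("EA-ECG features:\n")
  v <- unlist(x[FEATURE_NAMES])
  cat(sprintf("  %-6s %8.4f %s\n", FEATURE_NAMES, v,
              ifelse(grepl("^a_", FEATURE_NAMES), "mV", "s")), sep = "")
  if (!is.na(x$hr_bpm)) cat(sprintf("  hr     %8.2f bpm\n", x$hr_bpm))
  invisible(x)
}

#' Map waveform features and a heart rate to a beat model
#'
#' Inverts the feature-extraction conventions: the R-lobe center is placed at a
#' fixed fraction (0.4) of the beat period; the P and T lobe centers precede and
#' follow it by `t_P_R` and `t_R_T`; measured 5%-threshold widths are converted
#' back to lobe durations; and the QRS complex is expanded into Q, R, S lobes
#' with fixed geometry so that its measured extent reproduces `d_R`.
#'
#' @param features an [ecg_features()] object.
#' @param hr heart rate of the model, bpm (in (20, 250)).
#' @param fs sampling rate, Hz.
#' @return a [beat_model()].
#' @export
template_from_features <- function(features, hr, fs) {
  stopifnot(inherits(features, "ecg_features"))
  assert_scalar_num(hr, "hr", lower = 20 + 1e-9, upper = 250 - 1e-9)
  assert_scalar_num(fs, "fs", lower = 1e-6)
  period <- 60 / hr
  rc <- R_CENTER_FRAC * period
  r_lobe <- features$d_R / QRS_EXTENT_PER_RLOBE
  if (!is.finite(r_lobe) || r_lobe <= 0) stopf("QRS duration must be > 0")
  seg <- list()
  add <- function(label, amp, dur, center) {
    if (dur <= 0) stopf("duration of segment %s must be > 0", label)
    data.frame(label = label, amp = amp, dur = dur,
               onset = center - dur / 2, base = 0)
  }
  if (!is.na(features$a_P) && features$a_P != 0) {
    if (is.na(features$d_P)) stopf("P amplitude nonzero but duration absent")
    seg$P <- add("P", features$a_P, features$d_P / LOBE_WIDTH_5PCT,
                 rc - features$t_P_R)
  }
  seg$Q <- add("Q", Q_AMP_FRAC * features$a_R, r_lobe / 2, rc - r_lobe)
  seg$R <- add("R", features$a_R, r_lobe, rc)
  seg$S <- add("S", S_AMP_FRAC * features$a_R, r_lobe / 2, rc + r_lobe)
  if (!is.na(features$a_T) && features$a_T != 0) {
    if (is.na(features$d_T)) stopf("T amplitude nonzero but duration absent")
    seg$T <- add("T", features$a_T, features$d_T / LOBE_WIDTH_5PCT,
                 rc + features$t_R_T)
  }
  beat_model(do.call(rbind, seg), period, fs)
}

#' Heart rate from R-peak times
#'
#' @param rpeak_times strictly increasing R-peak times, seconds.
#' @return heart rate in bpm, `60 / mean(RR)`.
#' @export
heart_rate_from_rpeaks <- function(rpeak_times) {
  if (length(rpeak_times) < 2L)
    stopf("need at least 2 R peaks to measure a heart rate")
  d <- diff(rpeak_times)
  if (any(d <= 0)) stopf("R-peak times must be strictly increasing")
  60 / mean(d)
}

#' Read / write a feature file
#'
#' Features are stored as flat JSON with keys `a_P, d_P, t_P_R, a_R, d_R,
#' t_R_T, a_T, d_T, hr_bpm` (mV / s / bpm).
#'
#' @param features an [ecg_features()] object.
#' @param path file path.
#' @return `read_features` returns an `ecg_features` object;
#'   `write_features` returns `path` invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "ecg_features"))
  jsonlite::write_json(features[c(FEATURE_NAMES, "hr_bpm")], path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  miss <- setdiff(FEATURE_NAMES, names(x))
  if (length(miss)) stopf("feature file lacks keys: %s", paste(miss, collapse = ", "))
  x <- lapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  do.call(ecg_features, c(x[FEATURE_NAMES],
                          list(hr_bpm = if (is.null(x$hr_bpm)) NA_real_ else x$hr_bpm)))
}
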