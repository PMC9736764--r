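# Performance indexes: SNR in/out/improvement, exact dynamic time warping with
# warp path and percent distance, a cross-correlation similarity index,
# per-feature difference percentages with their similarity vector, and the
# weighted distortion assessment (WDA) index with its four canonical weight
# presets.

#' Signal-to-noise ratio report
#'
#' `SNR_in = 10 log10(sum(clean^2) / sum((contaminated - clean)^2))` in dB,
#' `SNR_out` likewise for the denoised signal, and
#' `SNR_imp = SNR_out - SNR_in` exactly.
#'
#' @param clean clean reference signal (ground truth or EA-proxy), mV.
#' @param contaminated contaminated signal, mV.
#' @param denoised denoised signal, mV.
#' @param clean_source label recorded in the report (`"ground-truth"` or
#'   `"EA-proxy"`).
#' @return an object of class `snr_report` with `snr_in`, `snr_out`,
#'   `snr_imp` (dB).
#' @export
snr_report <- function(clean, contaminated, denoised,
                       clean_source = "ground-truth") {
  if (length(clean) != length(contaminated) || length(clean) != length(denoised))
    stopf("clean, contaminated and denoised must have equal length")
  if (all(clean == 0)) stopf("clean signal is identically zero")
  snr <- function(x) {
    err <- x - clean
    if (all(err == 0)) {
      warnf("signal equals the clean reference; SNR is infinite")
      return(Inf)
    }
    10 * log10(sum(clean^2) / sum(err^2))
  }
  si <- snr(contaminated)
  so <- snr(denoised)
  structure(list(snr_in = si, snr_out = so, snr_imp = so - si,
                 clean_source = clean_source),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("SNR_in %.3f dB, SNR_out %.3f dB, SNR_imp %.3f dB (clean: %s)\n",
              x$snr_in, x$snr_out, x$snr_imp, x$clean_source))
  invisible(x)
}

#' Ensemble-average proxy for a clean reference
#'
#' When no ground-truth clean signal exists, the mean beat is tiled at the
#' detected R positions to form a periodic clean proxy; SNR reports built on
#' it are flagged `"EA-proxy"`.
#'
#' @param x signal, mV.
#' @param fs sampling rate, Hz.
#' @return list with `signal` (the proxy) and `flag = "EA-proxy"`.
#' @export
ea_proxy_clean <- function(x, fs) {
  pk <- detect_r_peaks(x, fs)
  ens <- ensemble_average(x, pk)
  n_pre <- ens$fiducial_index - 1L
  L <- length(ens$mean_beat)
  base <- mean(ens$mean_beat[seq_len(max(1L, round(0.02 * fs)))])
  y <- rep(base, length(x))
  for (i in pk$indices) {
    lo <- i - n_pre
    hi <- lo + L - 1L
    src <- ens$mean_beat
    if (lo < 1) { src <- src[(2 - lo):L]; lo <- 1L }
    if (hi > length(x)) { src <- src[seq_len(length(x) - lo + 1L)]; hi <- length(x) }
    y[lo:hi] <- src
  }
  list(signal = y, flag = "EA-proxy")
}

#' Dynamic time warping
#'
#' Exact dynamic-programming alignment under the absolute-difference local
#' cost and the three admissible moves (right, down, diagonal). The warp path
#' is backtraced from the end of the accumulated-cost matrix, preferring the
#' diagonal on ties. The percent distance normalizes the total cost by the
#' path length times the reference amplitude range.
#'
#' @param reference reference sequence.
#' @param test sequence under evaluation.
#' @param require_percent if `TRUE` (default) a constant reference (zero
#'   amplitude range) is an error because the percent distance is undefined;
#'   if `FALSE` the percent is reported as `NA` and only the cost and path
#'   are returned.
#' @return an object of class `dtw_result`: `total_cost`, `path` (2-column
#'   matrix of 1-based index pairs from (1,1) to (m,n)), `aligned_ref`,
#'   `aligned_test`, `percent_distance`.
#' @export
dtw <- function(reference, test, require_percent = TRUE) {
  m <- length(reference)
  n <- length(test)
  if (m == 0 || n == 0) stopf("sequences must be non-empty")
  if (as.double(m) * n > 4e6)
    stopf("DTW matrix %d x %d is too large; compare ensemble-average beats instead",
          m, n)
  D <- abs(outer(reference, test, `-`))
  C <- matrix(0, m, n)
  C[1, ] <- cumsum(D[1, ])
  C[, 1] <- cumsum(D[, 1])
  if (m > 1 && n > 1) {
    # fill the interior along anti-diagonals (vectorized over each diagonal)
    for (s in 4:(m + n)) {
      x <- max(2, s - n):min(m, s - 2)
      if (x[1] > x[length(x)]) next
      i <- x + (s - x - 1) * m
      C[i] <- D[i] + pmin(C[i - 1], C[i - m], C[i - m - 1])
    }
  }
  # backtrace, diagonal preferred on ties
  path <- matrix(0L, m + n, 2)
  k <- 1L
  x <- m; y <- n
  path[k, ] <- c(x, y)
  while (x > 1 || y > 1) {
    if (x == 1) y <- y - 1
    else if (y == 1) x <- x - 1
    else {
      cand <- c(C[x - 1, y - 1], C[x - 1, y], C[x, y - 1])
      j <- which.min(cand)  # diagonal first on ties
      if (j == 1) { x <- x - 1; y <- y - 1 }
      else if (j == 2) x <- x - 1
      else y <- y - 1
    }
    k <- k + 1L
    path[k, ] <- c(x, y)
  }
  path <- path[k:1, , drop = FALSE]
  rng <- max(reference) - min(reference)
  pd <- if (rng == 0) {
    if (require_percent) stopf("constant reference: percent distance undefined")
    NA_real_
  } else 100 * C[m, n] / (nrow(path) * rng)
  structure(list(total_cost = C[m, n], path = path,
                 aligned_ref = reference[path[, 1]],
                 aligned_test = test[path[, 2]],
                 percent_distance = pd),
            class = "dtw_result")
}

#' Mean per-beat DTW percent distance of a signal against a reference beat
#'
#' Epochs the signal around its detected R peaks (same 0.4/0.6 RR window as
#' the ensemble average), computes the DTW percent distance between the
#' reference beat and every individual beat, and averages. Unlike a distance
#' on the ensemble-average beat (where averaging itself cancels artifact),
#' this reflects the beat-to-beat contamination of the signal.
#'
#' @param x signal, mV.
#' @param fs sampling rate, Hz.
#' @param ref_beat reference beat samples (R at 0.4 of the beat, as produced
#'   by [synthesize_beat()] on a [template_from_features()] model).
#' @return list with `percent` (mean over beats), `per_beat`, `n_beats`.
#' @export
dtw_beat_distance <- function(x, fs, ref_beat) {
  pk <- detect_r_peaks(x, fs)
  rr <- diff(pk$indices)
  rrmed <- stats::median(rr)
  n_pre <- round(EA_WINDOW_FRACS[[1]] * rrmed)
  n_post <- round(EA_WINDOW_FRACS[[2]] * rrmed)
  usable <- pk$indices[pk$indices - n_pre >= 1 &
                         pk$indices + n_post - 1 <= length(x)]
  if (length(usable) < 2) stopf("fewer than 2 usable beats")
  per <- vapply(usable, function(i) {
    dtw(ref_beat, x[(i - n_pre):(i + n_post - 1)])$percent_distance
  }, numeric(1))
  list(percent = mean(per), per_beat = per, n_beats = length(usable))
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("DTW: total cost %.4f over a path of %d steps; percent distance %.2f%%\n",
              x$total_cost, nrow(x$path), x$percent_distance))
  invisible(x)
}

# population z-score (variance with 1/N), so that a length-N self-comparison
# scores exactly sqrt(N) under the index below
zscore_pop <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Cross-correlation similarity index
#'
#' Both sequences are z-scored; the index is the maximum over lags (up to
#' +/- 20% of the reference length, so near-empty overlaps cannot dominate)
#' of the sliding dot product, divided by `sqrt(length(reference))`. A
#' length-N self-comparison scores `sqrt(N)`.
#'
#' @param reference,test numeric sequences (equal sampling rate).
#' @param max_lag_frac largest |lag| examined, as a fraction of the reference
#'   length.
#' @return scalar index; 0 (with a warning) for zero-variance input.
#' @export
cross_correlation_index <- function(reference, test, max_lag_frac = 0.2) {
  if (!length(reference) || !length(test)) stopf("sequences must be non-empty")
  z1 <- zscore_pop(reference)
  z2 <- zscore_pop(test)
  if (all(z1 == 0) || all(z2 == 0)) {
    warnf("zero-variance input; cross-correlation index set to 0")
    return(0)
  }
  cc <- stats::convolve(z1, z2, conj = TRUE, type = "open")
  # entry n2 + k of the open convolution is the dot product at lag k
  n1 <- length(z1); n2 <- length(z2)
  lag0 <- n2
  maxlag <- max(0L, floor(max_lag_frac * n1))
  lo <- max(1L, lag0 - maxlag)
  hi <- min(length(cc), lag0 + maxlag)
  max(cc[lo:hi]) / sqrt(n1)
}

#' Per-feature difference percentages and similarities
#'
#' `%difference_i = 100 |enhanced_i - rest_i| / |rest_i|` for each of the 8
#' waveform features; `similarity_i = (100 - %difference_i)/100`, clamped to
#' `[0, 1]`. Features whose resting value is zero, or absent in either set,
#' are excluded and flagged.
#'
#' @param rest resting [ecg_features()] (the reference).
#' @param enhanced features of the signal under evaluation.
#' @return an object of class `feature_diff`: `percent` and `similarity`
#'   (named 8-vectors, NA where excluded), `excluded` (names).
#' @export
feature_difference <- function(rest, enhanced) {
  stopifnot(inherits(rest, "ecg_features"), inherits(enhanced, "ecg_features"))
  r <- unlist(rest[FEATURE_NAMES])
  e <- unlist(enhanced[FEATURE_NAMES])
  pct <- rep(NA_real_, 8)
  names(pct) <- FEATURE_NAMES
  ok <- !is.na(r) & !is.na(e) & r != 0
  pct[ok] <- 100 * abs(e[ok] - r[ok]) / abs(r[ok])
  feature_diff_from_percent(pct)
}

#' @rdname feature_difference
#' @param percent named (or ordered) 8-vector of percent differences, e.g.
#'   reported column means from an external study.
#' @export
feature_diff_from_percent <- function(percent) {
  stopifnot(length(percent) == 8)
  pct <- as.numeric(percent)
  names(pct) <- FEATURE_NAMES
  sim <- pmin(pmax((100 - pct) / 100, 0), 1)
  structure(list(percent = pct, similarity = sim,
                 excluded = FEATURE_NAMES[is.na(pct)]),
            class = "feature_diff")
}

#' @export
print.feature_diff <- function(x, ...) {
  cat("Feature differences (%) and similarities:\n")
  print(round(rbind(percent = x$percent, similarity = x$similarity), 4))
  if (length(x$excluded))
    cat("excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' WDA feature-weight presets
#'
#' The four canonical cases: equal weights (all 1); and P-amplitude,
#' QRS-amplitude or T-amplitude emphasized at 0.9 with all other weights 0.5.
#' Weight names follow the feature order `a_P, d_P, t_P_R, a_R, d_R, t_R_T,
#' a_T, d_T`.
#'
#' @param case preset name.
#' @return named numeric 8-vector of weights in `[0, 1]`.
#' @export
wda_weights <- function(case = c("equal", "p_amplitude", "qrs_amplitude",
                                 "t_amplitude")) {
  case <- match.arg(case)
  w <- switch(case,
              equal = rep(1, 8),
              p_amplitude = c(0.9, rep(0.5, 7)),
              qrs_amplitude = c(rep(0.5, 3), 0.9, rep(0.5, 4)),
              t_amplitude = c(rep(0.5, 6), 0.9, 0.5))
  names(w) <- FEATURE_NAMES
  w
}

#' Weighted distortion assessment (WDA) index
#'
#' `WDA = sum(w_i s_i) / sqrt(sum(w_i^2))`: the similarity vector projected on
#' the weight direction. Higher values mean lower waveform distortion; the
#' maximum under the equal-weight preset is `8 / sqrt(8)`.
#'
#' @param diff a `feature_diff` (complete: no excluded features).
#' @param weights numeric 8-vector of weights in `[0, 1]`, e.g. from
#'   [wda_weights()].
#' @return scalar WDA value.
#' @export
wda <- function(diff, weights = wda_weights("equal")) {
  stopifnot(inherits(diff, "feature_diff"))
  if (length(weights) != 8) stopf("weights must have 8 entries")
  if (any(weights < 0 | weights > 1)) stopf("weights must lie in [0, 1]")
  if (all(weights == 0)) stopf("weight vector must not be all zero")
  s <- diff$similarity
  if (anyNA(s)) stopf("similarity vector incomplete (excluded: %s)",
                      paste(diff$excluded, collapse = ", "))
  sum(weights * s) / sqrt(sum(weights^2))
}

#' Full evaluation report for a denoised record channel
#'
#' Computes every index on one denoised signal: the SNR report (against ground
#' truth when available, else the EA-proxy), the mean per-beat DTW percent
#' distance against the resting reference beat, the cross-correlation index
#' against the reference beat train, the 8 feature differences, and the WDA
#' index under all four presets.
#'
#' @param contaminated contaminated channel, mV.
#' @param denoised denoised channel, mV.
#' @param fs sampling rate, Hz.
#' @param rest_features resting [ecg_features()].
#' @param clean optional ground-truth clean signal.
#' @return an object of class `evaluation_report`.
#' @export
evaluate_denoising <- function(contaminated, denoised, fs, rest_features,
                               clean = NULL) {
  stopifnot(inherits(rest_features, "ecg_features"))
  if (is.null(clean)) {
    proxy <- ea_proxy_clean(contaminated, fs)
    snr <- snr_report(proxy$signal, contaminated, denoised,
                      clean_source = proxy$flag)
  } else {
    snr <- snr_report(clean, contaminated, denoised)
  }
  pk <- detect_r_peaks(denoised, fs)
  hr <- heart_rate_from_rpeaks(pk$times)
  ens <- ensemble_average(denoised, pk)
  ref_beat <- synthesize_beat(template_from_features(rest_features, hr, fs))
  dtw_res <- dtw_beat_distance(denoised, fs, ref_beat$samples)
  ref_train <- reference_train(rest_features, hr, fs, length(denoised),
                               pk$times[1])
  cci <- cross_correlation_index(ref_train, denoised)
  fd <- feature_difference(rest_features, extract_features(ens))
  wda_vals <- vapply(c("equal", "p_amplitude", "qrs_amplitude", "t_amplitude"),
                     function(cs) {
                       tryCatch(wda(fd, wda_weights(cs)), error = function(e) NA_real_)
                     }, numeric(1))
  structure(list(snr = snr, dtw_percent = dtw_res$percent,
                 dtw = dtw_res, cross_correlation = cci,
                 feature_diff = fd, wda = wda_vals, hr_bpm = hr),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$snr)
  cat(sprintf("DTW percent distance (EA beat vs reference beat): %.2f%%\n",
              x$dtw_percent))
  cat(sprintf("Cross-correlation index: %.3f\n", x$cross_correlation))
  print(x$feature_diff)
  cat("WDA:", paste(sprintf("%s=%.3f", names(x$wda), x$wda), collapse = ", "), "\n")
  invisible(x)
}

# flat named list used by the CLI report writers
flatten_report <- function(rep) {
  c(list(snr_in = rep$snr$snr_in, snr_out = rep$snr$snr_out,
         snr_imp = rep$snr$snr_imp, clean_source = rep$snr$clean_source,
         dtw_percent = rep$dtw_percent,
         cross_correlation = rep$cross_correlation, hr_bpm = rep$hr_bpm),
    as.list(stats::setNames(rep$feature_diff$percent,
                            paste0("pct_", names(rep$feature_diff$percent)))),
    as.list(stats::setNames(rep$wda, paste0("wda_", names(rep$wda)))))
}
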