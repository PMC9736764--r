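# Daubechies-8 wavelet machinery: decimated (Mallat) DWT with periodic
# boundary for shrinkage denoising, and a stationary (undecimated) transform
# whose equal-length coefficient sequences feed the wavelet-ICA method.

# Daubechies order-8 (16-tap) orthonormal decomposition filters; standard
# published constants.
DB8_LO <- c(-0.00011747678412476953, 0.0006754494064505693,
            -0.00039174037337694705, -0.004870352993451574,
            0.008746094047405777, 0.013981027917398282,
            -0.044088253930794755, -0.017369301001807547,
            0.12874742662047847, 0.0004724845739132828,
            -0.2840155429615469, -0.015829105256349306,
            0.5853546836542067, 0.6756307362972898,
            0.31287159091429995, 0.05441584224310401)
DB8_HI <- rev(DB8_LO) * (-1)^(seq_along(DB8_LO))

wavelet_filters <- function(family) {
  switch(family,
         db8 = list(lo = DB8_LO, hi = DB8_HI),
         stopf("unsupported wavelet family '%s' (available: db8)", family))
}

#' Wavelet denoising specification
#'
#' @param family mother wavelet (currently the Daubechies order-8 family).
#' @param levels decomposition depth.
#' @param threshold_rule `"riskshrink-minimax"` (minimax soft-threshold
#'   constant) or `"universal"` (sigma * sqrt(2 log N)).
#' @param threshold_mode `"soft"` or `"hard"`.
#' @return an object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(family = "db8", levels = 5,
                         threshold_rule = c("riskshrink-minimax", "universal"),
                         threshold_mode = c("soft", "hard")) {
  wavelet_filters(family)  # validates
  assert_scalar_num(levels, "levels", lower = 1)
  structure(list(family = family, levels = as.integer(levels),
                 threshold_rule = match.arg(threshold_rule),
                 threshold_mode = match.arg(threshold_mode)),
            class = "wavelet_spec")
}

# ---- decimated periodized DWT --------------------------------------------

dwt_step <- function(a, lo, hi) {
  N <- length(a)
  L <- length(lo)
  idx <- (outer(2 * (seq_len(N / 2) - 1), 0:(L - 1), `+`) %% N) + 1
  am <- matrix(a[idx], ncol = L)
  list(ca = as.numeric(am %*% lo), cd = as.numeric(am %*% hi))
}

idwt_step <- function(ca, cd, lo, hi) {
  # adjoint of the orthonormal analysis step
  N <- 2 * length(ca)
  L <- length(lo)
  out <- numeric(N)
  base <- 2 * (seq_along(ca) - 1)
  for (m in 0:(L - 1)) {
    pos <- ((base + m) %% N) + 1
    out[pos] <- out[pos] + lo[m + 1] * ca + hi[m + 1] * cd
  }
  out
}

# pad by reflecting the tail so length is a multiple of 2^levels
pad_pow2 <- function(x, levels) {
  N <- length(x)
  block <- 2^levels
  Np <- ceiling(N / block) * block
  if (Np == N) return(list(x = x, n = N))
  extra <- Np - N
  pad <- rev(x)[seq_len(min(extra, N))]
  while (length(pad) < extra) pad <- c(pad, rev(pad))[seq_len(extra)]
  list(x = c(x, pad), n = N)
}

dwt_decompose <- function(x, family, levels) {
  f <- wavelet_filters(family)
  a <- x
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    st <- dwt_step(a, f$lo, f$hi)
    a <- st$ca
    details[[j]] <- st$cd
  }
  list(approx = a, details = details, family = family)
}

dwt_reconstruct <- function(dec) {
  f <- wavelet_filters(dec$family)
  a <- dec$approx
  for (j in rev(seq_along(dec$details)))
    a <- idwt_step(a, dec$details[[j]], f$lo, f$hi)
  a
}

riskshrink_lambda <- function(sigma, N, rule) {
  if (rule == "universal") return(sigma * sqrt(2 * log(N)))
  if (N > 32) sigma * (0.3936 + 0.1829 * log2(N)) else 0
}

shrink <- function(d, lambda, mode) {
  if (mode == "soft") sign(d) * pmax(abs(d) - lambda, 0)
  else d * (abs(d) > lambda)
}

#' Wavelet-shrinkage denoising
#'
#' Multilevel Daubechies-8 decomposition (Mallat pyramid, periodic boundary);
#' each detail level is thresholded with the RiskShrink minimax rule
#' (lambda = sigma * (0.3936 + 0.1829 log2 N) for N > 32, else 0; noise scale
#' sigma = median(|d1|)/0.6745 from the finest detail level) and soft
#' shrinkage by default, then the signal is re-synthesized.
#'
#' @param x numeric signal.
#' @param spec a [wavelet_spec()].
#' @return denoised signal, same length as `x`.
#' @export
wavelet_shrinkage <- function(x, spec = wavelet_spec()) {
  stopifnot(inherits(spec, "wavelet_spec"))
  N <- length(x)
  if (N < 2^spec$levels)
    stopf("signal length %d < 2^levels; reduce depth to at most %d",
          N, max(1, floor(log2(N))))
  L <- length(wavelet_filters(spec$family)$lo)
  if (N / 2^spec$levels < L)
    stopf("signal too short for depth %d with a %d-tap filter; try levels <= %d",
          spec$levels, L, max(1, floor(log2(N / L))))
  p <- pad_pow2(x, spec$levels)
  dec <- dwt_decompose(p$x, spec$family, spec$levels)
  # noise scale from the finest detail level, where the smooth cardiac
  # waveform contributes least; coarser levels would conflate signal energy
  # with noise and over-shrink the P and T waves
  sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
  dec$details <- lapply(dec$details, function(d) {
    shrink(d, riskshrink_lambda(sigma, length(d), spec$threshold_rule),
           spec$threshold_mode)
  })
  dwt_reconstruct(dec)[seq_len(p$n)]
}

# ---- stationary (undecimated) transform ----------------------------------

# frequency responses of the level-j dilated filters on an N-grid
swt_freq <- function(h, N, j) {
  f <- numeric(N)
  f[(((seq_along(h) - 1) * 2^j) %% N) + 1] <- h
  stats::fft(f)
}

#' Stationary wavelet decomposition
#'
#' Undecimated transform: every coefficient sequence has the signal's length,
#' which is what lets them form the multichannel input of the wavelet-ICA
#' method. Implemented with circular convolution of dilated filters.
#'
#' @param x numeric signal.
#' @param family wavelet family.
#' @param levels decomposition depth.
#' @return matrix with `length(x)` rows and `levels + 1` columns
#'   (`d1 ... d<levels>`, `a<levels>`).
#' @export
swt_decompose <- function(x, family = "db8", levels = 5) {
  f <- wavelet_filters(family)
  N <- length(x)
  if (length(f$lo) * 2^(levels - 1) > N)
    stopf("levels too deep for signal length %d (dilated filter exceeds signal)", N)
  out <- matrix(0, N, levels + 1)
  colnames(out) <- c(paste0("d", seq_len(levels)), paste0("a", levels))
  A <- stats::fft(x)
  for (j in seq_len(levels)) {
    H <- swt_freq(f$lo, N, j - 1)
    G <- swt_freq(f$hi, N, j - 1)
    out[, j] <- Re(stats::fft(A * G, inverse = TRUE)) / N
    A <- A * H
  }
  out[, levels + 1] <- Re(stats::fft(A, inverse = TRUE)) / N
  out
}

#' @rdname swt_decompose
#' @param coeffs coefficient matrix from `swt_decompose`.
#' @return `swt_reconstruct` returns the re-synthesized signal.
#' @export
swt_reconstruct <- function(coeffs, family = "db8") {
  f <- wavelet_filters(family)
  levels <- ncol(coeffs) - 1
  N <- nrow(coeffs)
  A <- stats::fft(coeffs[, levels + 1])
  for (j in rev(seq_len(levels))) {
    H <- swt_freq(f$lo, N, j - 1)
    G <- swt_freq(f$hi, N, j - 1)
    A <- (A * Conj(H) + stats::fft(coeffs[, j]) * Conj(G)) / 2
  }
  Re(stats::fft(A, inverse = TRUE)) / N
}
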