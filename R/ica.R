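# Blind source separation for the redundant-channel model x = A s: FastICA-style
# fixed-point negentropy maximization (deflation, tanh contrast) on whitened,
# centered observations. Estimates are defined up to permutation, sign and
# scale; the pipeline resolves this by back-projecting selected sources through
# the estimated mixing matrix onto an observation channel.

#' Fit an independent component analysis model
#'
#' @param channels numeric matrix with one row per observed channel (or a list
#'   of equal-length numeric vectors). The square case n = m is used.
#' @param seed integer seed for the random initial unmixing vectors.
#' @param tol convergence tolerance on the unmixing-vector direction.
#' @param max_iter iteration cap per component.
#' @return an object of class `ica_model` with elements `A` (mixing matrix,
#'   m x n), `W` (end-to-end unmixing map, n x m), `S` (separated sources,
#'   n x N), `G` (`W %*% A`, identity up to numerical error), `center`
#'   (channel means).
#' @export
fit_ica <- function(channels, seed = 1L, tol = 1e-6, max_iter = 1000L) {
  if (is.list(channels) && !is.matrix(channels)) {
    if (length(unique(lengths(channels))) != 1)
      stopf("all channels must have equal length")
    channels <- do.call(rbind, channels)
  }
  stopifnot(is.matrix(channels))
  m <- nrow(channels)
  N <- ncol(channels)
  if (m < 2) stopf("need at least 2 channels")
  if (N < 10 * m) stopf("need at least 10 * m samples (have %d, need %d)", N, 10 * m)

  center <- rowMeans(channels)
  X <- channels - center
  C <- tcrossprod(X) / N
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values))
    stopf("channel set is rank-deficient (duplicated or linearly dependent channels)")
  K <- diag(1 / sqrt(eg$values), m) %*% t(eg$vectors)
  Z <- K %*% X

  U <- matrix(0, m, m)
  with_local_seed(seed, {
    for (i in seq_len(m)) {
      if (i == m && m > 1) {
        # the final deflation direction is the orthogonal complement of the
        # previous ones (unique up to sign); no iteration needed
        U[m, ] <- qr.Q(qr(t(U[seq_len(m - 1), , drop = FALSE])),
                       complete = TRUE)[, m]
        break
      }
      converged <- FALSE
      for (try in 1:5) {
        w <- stats::rnorm(m)
        if (i > 1) w <- w - t(U[seq_len(i - 1), , drop = FALSE]) %*%
            (U[seq_len(i - 1), , drop = FALSE] %*% w)
        w <- w / sqrt(sum(w^2))
        prev_delta <- Inf
        for (it in seq_len(max_iter)) {
          u <- as.numeric(crossprod(w, Z))
          gu <- tanh(u)
          w_new <- Z %*% gu / N - mean(1 - gu^2) * w
          if (i > 1) w_new <- w_new - t(U[seq_len(i - 1), , drop = FALSE]) %*%
              (U[seq_len(i - 1), , drop = FALSE] %*% w_new)
          nw <- sqrt(sum(w_new^2))
          if (nw < 1e-12) break
          w_new <- as.numeric(w_new) / nw
          delta <- abs(1 - abs(sum(w_new * w)))
          if (delta < tol) { w <- w_new; converged <- TRUE; break }
          if (delta > 0.999 * prev_delta) {
            # stalled two-cycle: damp by averaging with the previous direction
            w_new <- w_new + sign(sum(w_new * w)) * w
            if (i > 1) w_new <- w_new - t(U[seq_len(i - 1), , drop = FALSE]) %*%
                (U[seq_len(i - 1), , drop = FALSE] %*% w_new)
            w_new <- as.numeric(w_new) / sqrt(sum(w_new^2))
          }
          prev_delta <- delta
          w <- w_new
        }
        if (converged) break
      }
      if (!converged) {
        if (i == 1)
          stopf("ICA did not converge for component %d (tolerance %g, %d iterations)",
                i, tol, max_iter)
        # the remaining deflation subspace is essentially Gaussian (flat
        # contrast), so no preferred directions exist: complete with an
        # orthonormal basis of the complement
        Q <- qr.Q(qr(t(U[seq_len(i - 1), , drop = FALSE])), complete = TRUE)
        U[i:m, ] <- t(Q[, i:m, drop = FALSE])
        break
      }
      U[i, ] <- w
    }
  })
  W <- U %*% K
  S <- W %*% X
  A <- solve(W)
  structure(list(A = A, W = W, S = S, G = W %*% A, center = center),
            class = "ica_model")
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf("ICA model: %d sources x %d samples\n", nrow(x$S), ncol(x$S)))
  cat("mixing matrix A:\n")
  print(round(x$A, 4))
  invisible(x)
}

#' Back-reconstruct an observation channel from selected sources
#'
#' Zeroes every source outside `keep` and maps back through the mixing matrix,
#' returning the chosen observation row in its original (centered) amplitude
#' frame. This resolves the sign/scale ambiguity of the separated sources.
#'
#' @param model an `ica_model` from [fit_ica()].
#' @param keep indices of sources to retain (non-empty).
#' @param channel observation row to reconstruct.
#' @return numeric vector: the centered reconstruction of that channel.
#' @export
back_reconstruct <- function(model, keep, channel = 1L) {
  stopifnot(inherits(model, "ica_model"))
  n <- nrow(model$S)
  if (!length(keep)) stopf("`keep` must name at least one source")
  if (any(keep < 1 | keep > n)) stopf("source index out of range 1..%d", n)
  if (channel < 1 || channel > nrow(model$A)) stopf("invalid channel index")
  S0 <- model$S
  S0[setdiff(seq_len(n), keep), ] <- 0
  as.numeric(model$A[channel, , drop = FALSE] %*% S0)
}

#' Select the cardiac component by reference correlation
#'
#' Computes |Pearson r| between each separated source and a reference beat
#' train, and selects the source with the highest correlation (ties broken by
#' the lowest index). A zero-variance source scores 0.
#'
#' @param model an `ica_model`.
#' @param reference numeric reference signal, same length as the sources.
#' @param reference_hr optional heart rate (bpm) the reference was built at.
#' @return an object of class `selection_report`: `correlations`,
#'   `selected_index`, `reference_hr`, `low_confidence`.
#' @export
select_component <- function(model, reference, reference_hr = NA_real_) {
  stopifnot(inherits(model, "ica_model"))
  if (length(reference) != ncol(model$S))
    stopf("reference length (%d) must equal source length (%d)",
          length(reference), ncol(model$S))
  corrs <- apply(model$S, 1, function(s) {
    if (stats::sd(s) == 0 || stats::sd(reference) == 0) return(0)
    abs(stats::cor(s, reference))
  })
  structure(list(correlations = unname(corrs),
                 selected_index = unname(which.max(corrs)),
                 reference_hr = reference_hr,
                 low_confidence = !any(corrs > 0)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Component selection: source %d (|r| = %.3f)%s\n",
              x$selected_index, x$correlations[x$selected_index],
              if (x$low_confidence) " [low confidence]" else ""))
  cat("  |r| per source:", paste(sprintf("%.3f", x$correlations), collapse = " "), "\n")
  invisible(x)
}
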