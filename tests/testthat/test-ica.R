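test_that("a 2x2 Laplacian mixture is unmixed almost exactly", {
  set.seed(5)
  n <- 3000
  s1 <- rexp(n) - rexp(n)
  s2 <- rexp(n) - rexp(n)
  A <- matrix(c(1, 0.5, 0.5, 1), 2)
  mod <- fit_ica(A %*% rbind(s1, s2), seed = 2)
  cc <- abs(cor(t(mod$S), cbind(s1, s2)))
  # best match over permutation/sign
  expect_gt(max(cc[1, ]), 0.99)
  expect_gt(max(cc[2, ]), 0.99)
  expect_false(which.max(cc[1, ]) == which.max(cc[2, ]))
})

test_that("already-independent channels give a signed permutation gain matrix", {
  set.seed(6)
  X <- rbind(rexp(2000) - rexp(2000), rexp(2000) - rexp(2000))
  mod <- fit_ica(X, seed = 3)
  # identity mixing: the end-to-end unmixing map (row-normalized) must be a
  # signed permutation up to tolerance
  G <- abs(mod$W / apply(abs(mod$W), 1, max))
  for (i in 1:2) expect_lt(min(G[i, ]), 0.05)
  expect_false(which.max(G[1, ]) == which.max(G[2, ]))
})

test_that("the fixed-point solution matches a brute-force rotation search", {
  # 2-channel whitened problem: ICA reduces to one rotation angle; the
  # negentropy surrogate E[log cosh u] is scanned exhaustively
  set.seed(7)
  n <- 4000
  s <- rbind(rexp(n) - rexp(n), runif(n, -sqrt(3), sqrt(3)))
  A <- matrix(c(1, 0.3, -0.4, 1), 2)
  X <- A %*% s
  mod <- fit_ica(X, seed = 4)
  Xc <- X - rowMeans(X)
  eg <- eigen(tcrossprod(Xc) / n, symmetric = TRUE)
  Z <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors) %*% Xc
  angles <- seq(0, pi, by = pi / 3600)
  crit <- vapply(angles, function(a) {
    u <- cos(a) * Z[1, ] + sin(a) * Z[2, ]
    (mean(log(cosh(u))) - 0.3746)^2  # distance from the Gaussian value
  }, numeric(1))
  best <- angles[which.max(crit)]
  U <- mod$W %*% eg$vectors %*% diag(sqrt(eg$values))  # rotation in whitened frame
  ang <- atan2(U[, 2], U[, 1]) %% pi
  delta <- min(pmin(abs(ang - best), pi - abs(ang - best)))
  expect_lt(delta, 2 * pi / 180)
})

test_that("degenerate channel sets are rejected", {
  set.seed(8)
  x <- rnorm(500)
  expect_error(fit_ica(rbind(x, x), seed = 1), "rank-deficient")
  expect_error(fit_ica(rbind(x[1:10], x[1:10] * 2), seed = 1), "10 \\* m")
  expect_error(fit_ica(matrix(x, 1), seed = 1), "at least 2")
})

test_that("back-reconstruction with all sources kept restores the centered channel", {
  sim <- sim_fixture(snr = -5, seed = 11)
  ch <- rbind(sim$record$data[, 1], sim$record$data[, 2],
              t(sim$record$data[, 3:5]))
  mod <- fit_ica(ch, seed = 9)
  rec <- back_reconstruct(mod, keep = 1:5, channel = 1)
  target <- ch[1, ] - mean(ch[1, ])
  expect_lt(max(abs(rec - target)) / max(abs(target)), 1e-6)
  expect_error(back_reconstruct(mod, integer(0), 1), "at least one")
})

test_that("keeping only the cardiac component isolates the clean source", {
  sim <- sim_fixture(snr = -5, seed = 11)
  clean <- sim$truth$clean_ecg
  ch <- rbind(sim$record$data[, 1], sim$record$data[, 2],
              t(sim$record$data[, 3:5]))
  mod <- fit_ica(ch, seed = 9)
  ic <- which.max(abs(apply(mod$S, 1, cor, y = clean)))
  kept <- back_reconstruct(mod, keep = ic, channel = 1)
  expect_gt(cor(kept, clean), 0.9)
  rest <- back_reconstruct(mod, keep = setdiff(1:5, ic), channel = 1)
  expect_lt(abs(cor(rest, clean)), 0.3)
})

test_that("component selection is by highest |r| with sane degenerate behavior", {
  set.seed(12)
  ref <- sin(seq(0, 20 * pi, length.out = 500))
  mod <- structure(list(S = rbind(rnorm(500), ref, rnorm(500)),
                        A = diag(3), W = diag(3), G = diag(3),
                        center = rep(0, 3)), class = "ica_model")
  sel <- select_component(mod, ref)
  expect_equal(sel$selected_index, 2L)
  expect_equal(max(sel$correlations), 1, tolerance = 1e-12)
  mod0 <- mod; mod0$S <- matrix(0, 3, 500)
  sel0 <- select_component(mod0, ref)
  expect_true(all(sel0$correlations == 0))
  expect_true(sel0$low_confidence)
  expect_error(select_component(mod, ref[-1]), "length")
})
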