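test_that("random partitions are disjoint, equal-sized and seeded", {
  s <- make_partitions(3600, 8, seed = 4)
  expect_equal(s$sizes, rep(450, 8))
  expect_equal(sum(table(s$assignment)), 3600)
  s2 <- make_partitions(3600, 8, seed = 4)
  expect_identical(s$assignment, s2$assignment)
  s3 <- make_partitions(3600, 8, seed = 5)
  expect_false(identical(s$assignment, s3$assignment))
})

test_that("remainder rows are dropped (or redistributed on request)", {
  s <- suppressMessages(make_partitions(10, 3, seed = 1))
  expect_equal(s$sizes, c(3, 3, 3))
  expect_equal(length(s$dropped), 1)
  s2 <- make_partitions(10, 3, seed = 1, redistribute = TRUE)
  expect_equal(sort(s2$sizes), c(3, 3, 4))
  expect_equal(length(s2$dropped), 0)
  s1 <- make_partitions(7, 1)
  expect_equal(s1$sizes, 7)
})

test_that("partition assignments round-trip through the export table", {
  s <- suppressMessages(make_partitions(23, 4, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_partitions(s, path)
  s2 <- read_partitions(path)
  expect_identical(s2$assignment, s$assignment)
  expect_equal(s2$n_p, 4)
})

test_that("hat-matrix differences are idempotent projections with trace df1", {
  fx <- small_spatial(N = 45, range = 0.4, seed = 14, p_extra = 2)
  des <- pgls_design(fx$data$coords, fx$data$X, fx$model, n_p = 3,
                     reduced = list(drop = c("x1", "x2")), seed = 6)
  expect_equal(des$df1, 2)
  for (fr in des$parts) {
    S <- tcrossprod(fr$Q) - tcrossprod(fr$Q0)
    expect_lt(max(abs(S %*% S - S)), 1e-8)
    expect_equal(sum(diag(S)), 2, tolerance = 1e-8)
  }
})

test_that("self-pair whitened correlation is the identity; rho self-values are 1", {
  fx <- small_spatial(N = 30, range = 0.5, seed = 3)
  des <- pgls_design(fx$data$coords, fx$data$X, fx$model, n_p = 2,
                     reduced = list(drop = "x1"), seed = 9)
  fr <- des$parts[[1]]
  C_ii <- fx$C[fr$idx, fr$idx]
  R_ii <- cross_whitened_correlation(fr$D, fr$D, C_ii)
  expect_lt(max(abs(R_ii - diag(fr$m))), 1e-8)
  expect_equal(rho_ssr(fr$Q, fr$Q0, fr$Q, fr$Q0, R_ii), 1, tolerance = 1e-8)
  expect_equal(rho_sse(fr$Q, fr$Q, R_ii), 1, tolerance = 1e-8)
})

test_that("zero cross-correlation gives zero rho and zero coefficient covariance", {
  fx <- small_spatial(N = 30, range = 0.5, seed = 3)
  des <- pgls_design(fx$data$coords, fx$data$X, fx$model, n_p = 2,
                     reduced = list(drop = "x1"), seed = 9)
  f1 <- des$parts[[1]]; f2 <- des$parts[[2]]
  R0 <- matrix(0, f1$m, f2$m)
  expect_equal(rho_ssr(f1$Q, f1$Q0, f2$Q, f2$Q0, R0), 0)
  expect_equal(rho_sse(f1$Q, f2$Q, R0), 0)
})

test_that("Kronecker-free rho evaluation equals the explicit vec/Kronecker oracle", {
  ## small enough to materialize R (x) R explicitly
  fx <- small_spatial(N = 14, range = 0.6, seed = 17)
  des <- suppressMessages(
    pgls_design(fx$data$coords, fx$data$X, fx$model, n_p = 2,
                reduced = list(drop = "x1"), seed = 1))
  f1 <- des$parts[[1]]; f2 <- des$parts[[2]]
  C_12 <- fx$C[f1$idx, f2$idx]
  R12 <- cross_whitened_correlation(f1$D, f2$D, C_12)
  S1 <- tcrossprod(f1$Q) - tcrossprod(f1$Q0)
  S2 <- tcrossprod(f2$Q) - tcrossprod(f2$Q0)
  oracle_ssr <- drop(t(as.vector(S1)) %*% kronecker(R12, R12) %*%
                       as.vector(S2)) / des$df1
  expect_equal(rho_ssr(f1$Q, f1$Q0, f2$Q, f2$Q0, R12), oracle_ssr,
               tolerance = 1e-10)
  I1 <- diag(f1$m) - tcrossprod(f1$Q)
  I2 <- diag(f2$m) - tcrossprod(f2$Q)
  oracle_sse <- drop(t(as.vector(I1)) %*% kronecker(R12, R12) %*%
                       as.vector(I2)) / sqrt(f1$df2 * f2$df2)
  expect_equal(rho_sse(f1$Q, f2$Q, R12), oracle_sse, tolerance = 1e-10)
})

test_that("rho is symmetric in the pair and bounded in [0 - eps, 1 + eps]", {
  fx <- small_spatial(N = 60, range = 0.5, seed = 23)
  des <- pgls_design(fx$data$coords, fx$data$X, fx$model, n_p = 3,
                     reduced = list(drop = "x1"), seed = 2)
  f1 <- des$parts[[1]]; f2 <- des$parts[[2]]
  C12 <- fx$C[f1$idx, f2$idx]
  R12 <- cross_whitened_correlation(f1$D, f2$D, C12)
  R21 <- cross_whitened_correlation(f2$D, f1$D, t(C12))
  expect_equal(rho_ssr(f1$Q, f1$Q0, f2$Q, f2$Q0, R12),
               rho_ssr(f2$Q, f2$Q0, f1$Q, f1$Q0, R21), tolerance = 1e-10)
  expect_true(all(des$cross$rho_ssr > -1e-8 & des$cross$rho_ssr < 1 + 1e-8))
  expect_true(all(des$cross$rho_sse > -1e-8 & des$cross$rho_sse < 1 + 1e-8))
})

test_that("cross statistics shrink toward zero as the range shrinks", {
  ## spatially structured predictor (latitude): the SSR projectors then
  ## align with the long-range error modes and rho tracks the range
  geom <- spatial_sim_geometry(8, 0.5)
  X <- cbind(1, lat = geom$x)
  stats <- vapply(c(0.5, 0.1, 0.02), function(rg) {
    m <- cor_model("exponential", range = rg)
    des <- pgls_design(geom$coords, X, m, n_p = 2,
                       reduced = list(drop = 2), seed = 2)
    c(des$cross$rho_ssr_mean, des$cross$rho_sse_mean)
  }, numeric(2))
  expect_true(all(diff(stats[1, ]) < 0))
  expect_true(all(diff(stats[2, ]) < 0))
  expect_lt(stats[1, 3], 0.05)
})

test_that("coefficient cross-covariance reduces to (U'U)^{-1} for the self pair", {
  fx <- small_spatial(N = 30, range = 0.5, seed = 3)
  C <- fx$C
  D <- whiten(C)
  fit <- gls_fit(fx$data$X, fx$data$y, D = D)
  V <- coef_cross_covariance(fit, fit, diag(30))
  expect_equal(V, chol2inv(chol(crossprod(fit$U))), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("pair budget selects the requested number of pairs", {
  fx <- small_spatial(N = 96, range = 0.4, seed = 33)
  des <- pgls_design(fx$data$coords, fx$data$X, fx$model, n_p = 8,
                     reduced = list(drop = "x1"), pair_budget = 15, seed = 3)
  expect_equal(nrow(des$cross$pairs), 15)            # 15 of 28
  des2 <- pgls_design(fx$data$coords, fx$data$X, fx$model, n_p = 2,
                      reduced = list(drop = "x1"), seed = 3)
  expect_equal(nrow(des2$cross$pairs), 1)
  expect_error(pgls_design(fx$data$coords, fx$data$X, fx$model, n_p = 2,
                           reduced = list(drop = "x1"), pair_budget = 0,
                           seed = 3),
               "pair_budget")
})

test_that("partitions too small for the model are rejected", {
  fx <- small_spatial(N = 12, range = 0.4, seed = 2, p_extra = 2)
  expect_error(pgls_design(fx$data$coords, fx$data$X, fx$model, n_p = 4,
                           reduced = list(drop = "x1"), seed = 1),
               "too small")
})

test_that("empirical cross-partition correlations match the analytic values", {
  ## two partitions of 40 under strong correlation; Monte-Carlo oracle
  fx <- small_spatial(N = 80, range = 0.4, seed = 51)
  des <- pgls_design(fx$data$coords, fx$data$X, fx$model, n_p = 2,
                     reduced = list(drop = "x1"), seed = 7)
  R <- chol(fx$C)
  nsim <- 2e4
  Y <- with_seed(91, crossprod(R, matrix(rnorm(80 * nsim), 80, nsim)))
  SSR <- SSE <- B <- matrix(0, nsim, 2)
  for (i in 1:2) {
    fr <- des$parts[[i]]
    Z <- fr$D %*% Y[fr$idx, ]
    cf <- crossprod(fr$Q, Z)
    c0 <- crossprod(fr$Q0, Z)
    SSE[, i] <- colSums(Z^2) - colSums(cf^2)
    SSR[, i] <- colSums(cf^2) - colSums(c0^2)
    B[, i] <- (backsolve(qr.R(fr$qr), cf)[order(fr$qr$pivot), ])[2, ]
  }
  expect_within(cor(SSR[, 1], SSR[, 2]), des$cross$rho_ssr, 0.03)
  expect_within(cor(SSE[, 1], SSE[, 2]), des$cross$rho_sse, 0.03)
  expect_within(cor(B[, 1], B[, 2]), des$cross$coef_cor[1, 2], 0.03)
  ## whitened cross-correlation itself: E[A_i A_j'] = R_ij entrywise
  f1 <- des$parts[[1]]; f2 <- des$parts[[2]]
  A1 <- f1$D %*% Y[f1$idx, 1:1e4]
  A2 <- f2$D %*% Y[f2$idx, 1:1e4]
  R12 <- cross_whitened_correlation(f1$D, f2$D, fx$C[f1$idx, f2$idx])
  emp <- tcrossprod(A1, A2) / 1e4
  expect_lt(max(abs(emp - R12)), 0.06)   # ~4 MC se of a correlation at n=1e4
})
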