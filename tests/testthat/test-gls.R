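test_that("GLS with identity correlation reduces to OLS (coef, F, t)", {
  with_seed(11, {
    n <- 60
    X <- cbind(1, rnorm(n), rnorm(n))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    y <- 1 + 0.5 * X[, 2] + rnorm(n)
  })
  fit <- gls_fit(X, y, C = NULL)
  ols <- lm(y ~ X[, 2] + X[, 3])
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
  red <- gls_fit(X[, 1, drop = FALSE], y, C = NULL)
  ft <- f_test(fit, red)
  expect_equal(ft$statistic, unname(summary(ols)$fstatistic[1]),
               tolerance = 1e-10)
  tt <- t_test(fit, "x1")
  expect_equal(tt$statistic, unname(summary(ols)$coefficients["X[, 2]", 3]),
               tolerance = 1e-10)
  expect_equal(tt$p_value, unname(summary(ols)$coefficients["X[, 2]", 4]),
               tolerance = 1e-10)
})

test_that("whitened path agrees with the brute-force matrix-inverse oracle", {
  fx <- small_spatial(N = 6, range = 0.6, seed = 21)
  fit <- gls_fit(fx$data, C = fx$C)
  Ci <- solve(fx$C)
  X <- fx$data$X; y <- fx$data$y
  B <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  SSE <- drop(t(y - X %*% B) %*% Ci %*% (y - X %*% B))
  expect_equal(unname(fit$coefficients), unname(drop(B)), tolerance = 1e-8)
  expect_equal(fit$SSE, SSE, tolerance = 1e-8)
  V <- fit$MSE * solve(t(X) %*% Ci %*% X)
  expect_equal(unname(sqrt(diag(fit$coef_cov))), unname(sqrt(diag(V))),
               tolerance = 1e-8)
})

test_that("whitened and direct forms agree on random SPD instances up to N = 200", {
  for (N in c(25, 80, 200)) {
    fx <- small_spatial(N = N, range = 0.4, seed = N)
    fit <- gls_fit(fx$data, C = fx$C)
    Ci <- solve(fx$C)
    X <- fx$data$X; y <- fx$data$y
    B <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
    SSE <- drop(t(y - X %*% B) %*% Ci %*% (y - X %*% B))
    expect_lt(max(abs(fit$coefficients - B)), 1e-8)
    expect_lt(abs(fit$SSE - SSE) / SSE, 1e-8)
  }
})

test_that("perfect fit gives SSE = 0 and t-test guards degenerate input", {
  X <- cbind(1, 1:10)
  y <- drop(X %*% c(2, 3))
  fit <- gls_fit(X, y, C = NULL)
  expect_lt(fit$SSE, 1e-18)
  expect_error(t_test(fit, 5), "unknown coefficient")
  fit$coef_cov[] <- 0                  # exactly-zero standard error
  expect_error(t_test(fit, 2), "standard error")
})

test_that("sums of squares decompose additively: SSR(1-0) + SSE = SSE0", {
  fx <- small_spatial(N = 50, range = 0.3, seed = 5, p_extra = 2)
  D <- whiten(fx$C)
  full <- gls_fit(fx$data$X, fx$data$y, D = D)
  red <- gls_fit(fx$data$X[, 1, drop = FALSE], fx$data$y, D = D)
  SSR <- red$SSE - full$SSE
  expect_equal(SSR + full$SSE, red$SSE)   # exact identity
  expect_gte(SSR, 0)
  ## empty reduced model: SSE0 = Z'Z
  red0 <- gls_fit(matrix(numeric(0), 50, 0), fx$data$y, D = D)
  expect_equal(red0$SSE, sum((D %*% fx$data$y)^2))
})

test_that("f_test equals t_test squared for a single dropped coefficient", {
  fx <- small_spatial(N = 40, range = 0.3, seed = 9)
  D <- whiten(fx$C)
  full <- gls_fit(fx$data$X, fx$data$y, D = D)
  red <- gls_fit(fx$data$X[, 1, drop = FALSE], fx$data$y, D = D)
  expect_equal(t_test(full, 2)$statistic^2, f_test(full, red)$statistic,
               tolerance = 1e-10)
  expect_equal(t_test(full, 2)$p_value, f_test(full, red)$p_value,
               tolerance = 1e-10)
})

test_that("reduced = full gives statistic 0 and p-value 1", {
  fx <- small_spatial(N = 30, range = 0.3, seed = 2)
  D <- whiten(fx$C)
  full <- gls_fit(fx$data$X, fx$data$y, D = D)
  expect_error(f_test(full, full), "nested")
})

test_that("non-nested models are rejected", {
  with_seed(4, {
    X <- cbind(1, rnorm(30), rnorm(30))
    y <- rnorm(30)
  })
  full <- gls_fit(X[, 1:2], y, C = NULL)
  other <- gls_fit(X[, c(1, 3)], y, C = NULL)
  expect_error(f_test(full, other))
})

test_that("F and LRT p-values converge as df2 grows", {
  gaps <- vapply(c(20, 200, 2000), function(df2) {
    with_seed(df2, {
      N <- df2 + 2
      X <- cbind(1, rnorm(N))
      y <- rnorm(N)
    })
    full <- gls_fit(X, y, C = NULL)
    red <- gls_fit(X[, 1, drop = FALSE], y, C = NULL)
    abs(f_test(full, red)$p_value - lr_test(full, red)$p_value)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.002)
})

test_that("rank-deficient designs raise an error naming the collinear column", {
  X <- cbind(1, 1:20, 2 * (1:20))
  colnames(X) <- c("(Intercept)", "a", "b")
  expect_error(gls_fit(X, rnorm(20), C = NULL), "collinear")
})

test_that("restriction-matrix reduced designs span the constrained space", {
  ## H0: b1 = b2 via L = (0, 1, -1)
  with_seed(8, {
    X <- cbind(1, rnorm(50), rnorm(50))
    y <- 1 + X[, 2] + X[, 3] + rnorm(50)
  })
  X0 <- reduced_design(X, restrict = matrix(c(0, 1, -1), 1))
  expect_equal(ncol(X0), 2)
  full <- gls_fit(X, y, C = NULL)
  red <- gls_fit(X0, y, C = NULL)
  ft <- f_test(full, red)
  ## oracle: classical linear-hypothesis F on the same restriction
  ols_f <- lm(y ~ 0 + X)
  ols_r <- lm(y ~ 0 + I(X[, 1]) + I(X[, 2] + X[, 3]))
  f_or <- ((sum(resid(ols_r)^2) - sum(resid(ols_f)^2)) / 1) /
    (sum(resid(ols_f)^2) / (50 - 3))
  expect_equal(ft$statistic, f_or, tolerance = 1e-8)
})

test_that("null F p-values are uniform under a known correlation model", {
  fx <- small_spatial(N = 100, range = 0.2, seed = 31)
  D <- whiten(fx$C)
  R <- chol(fx$C)
  pv <- with_seed(99, vapply(seq_len(400), function(i) {
    y <- drop(crossprod(R, rnorm(100)))
    full <- gls_fit(fx$data$X, y, D = D)
    red <- gls_fit(fx$data$X[, 1, drop = FALSE], y, D = D)
    f_test(full, red)$p_value
  }, numeric(1)))
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.01)
})
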