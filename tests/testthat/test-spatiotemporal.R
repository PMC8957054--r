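test_that("least-squares pixel fit matches the closed-form slope", {
  z <- c(2.1, 2.9, 4.2, 5.1, 5.8, 7.2, 8.1, 8.8, 10.3, 10.9)
  ft <- fit_pixel_ls(z)
  t_ <- 1:10
  slope <- sum((t_ - mean(t_)) * (z - mean(z))) / sum((t_ - mean(t_))^2)
  expect_equal(ft$trend, slope, tolerance = 1e-12)
  expect_equal(ft$residuals, z - ft$intercept - ft$trend * t_)
  expect_equal(fit_pixel_ls(rep(3, 6))$trend, 0)
  expect_lt(max(abs(fit_pixel_ls(2 + 0.5 * (1:8))$residuals)), 1e-12)
  expect_error(fit_pixel_ls(rnorm(5), times = rep(1, 5)), "constant")
})

test_that("AR(1)-REML fit agrees with the nlme REML oracle", {
  skip_if_not_installed("nlme")
  with_seed(71, {
    for (k in 1:3) {
      T_ <- 30
      e <- as.numeric(arima.sim(list(ar = 0.5), T_))
      z <- 1 + 0.1 * (1:T_) + e
      ours <- fit_pixel_ar1_reml(z)
      df <- data.frame(z = z, t = 1:T_)
      ref <- nlme::gls(z ~ t, data = df,
                       correlation = nlme::corAR1(form = ~t),
                       method = "REML")
      beta_ref <- coef(ref$modelStruct$corStruct, unconstrained = FALSE)
      expect_within(ours$beta, unname(beta_ref), 1e-4)
      expect_within(ours$trend, unname(coef(ref)[2]), 1e-6)
    }
  })
})

test_that("REML beta is nearly unbiased and near LS for white-noise data", {
  bh <- with_seed(73, replicate(600, {
    z <- rnorm(60)
    fit_pixel_ar1_reml(z)$beta
  }))
  expect_within(mean(bh), 0, 0.03)
  with_seed(74, {
    z <- rnorm(400)
    expect_within(fit_pixel_ar1_reml(z)$trend, fit_pixel_ls(z)$trend, 2e-4)
  })
})

test_that("the REML objective is locally optimal at the reported beta", {
  with_seed(75, {
    z <- as.numeric(arima.sim(list(ar = 0.3), 40)) + 0.05 * (1:40)
  })
  ft <- fit_pixel_ar1_reml(z)
  nll <- function(b) partGLS:::ar1_reml_nll(b, z, seq_along(z))
  expect_lte(nll(ft$beta), nll(ft$beta + 0.01))
  expect_lte(nll(ft$beta), nll(ft$beta - 0.01))
})

test_that("analytic pair covariance recovers the AR(1) autocovariance at l = k", {
  pair <- analytic_pair_covariance(0.5, 0.5, 1, 4)
  oracle <- outer(1:4, 1:4, function(t, s) 0.5^abs(t - s)) / (1 - 0.25)
  expect_equal(pair$W, oracle, tolerance = 1e-12)
  ## no memory: W = cor_delta * I
  p0 <- analytic_pair_covariance(0, 0, 0.3, 5)
  expect_equal(p0$W, 0.3 * diag(5))
  expect_error(analytic_pair_covariance(1, 0.2, 0.5, 10), "nonstationary")
})

test_that("analytic pair covariance matches simulated cross-covariances", {
  bl <- 0.8; bk <- -0.4; cd <- 0.5; T_ <- 12
  W <- analytic_pair_covariance(bl, bk, cd, T_)$W
  sims <- with_seed(81, partGLS:::sim_ar1_pairs(2e5, bl, bk, cd, T_))
  emp <- crossprod(sims$el, sims$ek) / nrow(sims$el)
  expect_lt(max(abs(emp - W)), 0.03)
})

test_that("residual and trend correlations reproduce the analytic table", {
  ## equal beta: both correlations equal the innovation correlation
  for (T_ in c(10, 30, 100)) {
    pr <- analytic_pair_covariance(0.8, 0.8, 0.5, T_)
    expect_equal(cor_residuals_analytic(pr), 0.5, tolerance = 1e-12)
    expect_equal(cor_trend_analytic(pr), 0.5, tolerance = 1e-9)
  }
  ## strongly different beta, printed reference values
  p10 <- analytic_pair_covariance(0.8, -0.4, 0.5, 10)
  expect_equal(round(cor_residuals_analytic(p10), 2), 0.21)
  expect_equal(round(cor_trend_analytic(p10), 2), 0.25)
  p100 <- analytic_pair_covariance(0.8, 0, 0.5, 100)
  expect_equal(round(cor_residuals_analytic(p100), 2), 0.30)
  expect_equal(round(cor_trend_analytic(p100), 2), 0.47)
})

test_that("trend correlation exceeds residual correlation and grows with T", {
  ratios <- vapply(c(10, 30, 100), function(T_) {
    pr <- analytic_pair_covariance(0.8, -0.4, 0.5, T_)
    cor_trend_analytic(pr) / cor_residuals_analytic(pr)
  }, numeric(1))
  expect_true(all(ratios >= 1 - 1e-9))
  expect_true(all(diff(ratios) > 0))
})

test_that("range estimation recovers exact and noisy decay parameters", {
  d <- seq(0.005, 1, length.out = 200)
  v <- exp(-d / 0.1)
  m <- estimate_range_model(v, d)
  expect_within(m$range, 0.1, 1e-6)
  m2 <- estimate_range_model(exp(-(d / 0.2)^1.5), d, "exponential_power")
  expect_within(m2$range, 0.2, 1e-4)
  expect_within(m2$shape, 1.5, 1e-3)
  expect_warning(estimate_range_model(rep(0, length(d)), d), "near zero")
  expect_error(estimate_range_model(v[1:5], d[1:5]), "20")
})

test_that("range is recovered from simulated maps within 20 percent", {
  rhat <- with_seed(85, {
    geom <- spatial_sim_geometry(20, 0.1)
    vapply(1:5, function(k) {
      sim <- simulate_spatiotemporal(20, T_ = 30, beta = 0.2, r = 0.1,
                                     geometry = geom)
      pf <- fit_pixels(sim$zmat, sim$times, "reml")
      pc <- residual_cor_pairs(pf$residuals, sim$coords, 1500)
      estimate_range_model(pc$cor, pc$d)$range
    }, numeric(1))
  })
  expect_within(mean(rhat), 0.1, 0.02)
})

test_that("nugget ML recovers boundary and interior truths", {
  with_seed(87, {
    coords <- matrix(runif(2 * 150), 150, 2)
    m <- cor_model("exponential", range = 0.2)
    C <- build_correlation(coords, m)
    X <- matrix(1, 150, 1)
    ## pure nugget data: C = I
    est_iid <- estimate_nugget_ml(rnorm(150), X, coords, m)
    expect_gt(est_iid$nugget, 0.7)
    ## spatially correlated data with true nugget 0
    y_sp <- drop(crossprod(chol(C), rnorm(150)))
    est_sp <- estimate_nugget_ml(y_sp, X, coords, m)
    expect_lt(est_sp$nugget, 0.3)
    ## optimizer contract: reported optimum beats neighbors
    base <- exp(-cross_dist(coords) / 0.2); diag(base) <- 1
    ll <- function(nug) {
      Cn <- (1 - nug) * base; diag(Cn) <- 1
      R <- chol(Cn)
      W <- forwardsolve(t(R), cbind(X, y_sp))
      sse <- sum(lm.fit(W[, 1, drop = FALSE], W[, 2])$residuals^2)
      -0.5 * (150 * log(sse / 150) + 2 * sum(log(diag(R))))
    }
    nug <- est_sp$nugget
    expect_gte(ll(nug), ll(min(nug + 0.01, 0.999)) - 1e-6)
    expect_gte(ll(nug), ll(max(nug - 0.01, 0)) - 1e-6)
  })
})

test_that("the spatiotemporal pipeline runs end to end and reports all stages", {
  sim <- simulate_spatiotemporal(12, T_ = 20, beta = 0.2, r = 0.1,
                                 c_step = 0.3, trend_noise_sd = 0.1,
                                 seed = 9)
  st <- suppressMessages(
    spatiotemporal_gls(sim$zmat, sim$coords, sim$X,
                       reduced = list(drop = paste0("class", 2:4)),
                       n_p = 2, n_pairs = 800, seed = 11))
  expect_s3_class(st, "st_gls")
  expect_equal(nrow(st$pixel_fits), 144)
  expect_true(all(st$nuggets >= 0 & st$nuggets < 1))
  expect_true(st$lrt$p_value >= 0 && st$lrt$p_value <= 1)
  expect_equal(st$pg$df1, 3)
  ## strong class signal should be detected
  expect_lt(st$lrt$p_value, 0.05)
})
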