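## Synthetic-data generators and validation harnesses: the spatial
## regression-on-latitude design, the spatiotemporal land-cover-trend
## design, and runners reproducing the analytic/simulation tables and the
## type-I-error / power experiments.

#' Grid geometry and simulation Cholesky factor for the spatial design
#'
#' The map is an `n` x `n` pixel grid spanning the unit square (coordinates
#' `(row/n, col/n)`); ranges are standardized to the scale of the map:
#' `r = 0.03` means 3% of the map side.
#'
#' @param n grid side.
#' @param r range as a fraction of the map side.
#' @param nugget nugget of the simulated errors.
#' @return list: `coords`, `x` (latitude = row/n), `model` (absolute-range
#'   [cor_model()]), `R` (upper Cholesky factor of the correlation matrix),
#'   `n`, `r`.
#' @export
spatial_sim_geometry <- function(n = 60, r = 0.03, nugget = 0) {
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  coords <- cbind(x = g$row / n, y = g$col / n)
  model <- cor_model("exponential", range = r, nugget = nugget)
  C <- build_correlation(coords, model)
  list(coords = coords, x = g$row / n, model = model,
       R = chol_jitter(C), n = n, r = r)
}

#' Simulate the spatial regression design
#'
#' `y = b0 + b x + gamma` on an `n` x `n` grid, where `x` is the latitude
#' (row/n) and the errors are multivariate Gaussian with exponential spatial
#' correlation and standard deviation `sigma`.
#'
#' The error standard deviation is not a free dial: the default reproduces
#' the validation design, where the full-map GLS power at `b = 10` pins the
#' error scale at `sigma = 17.1` for both ranges under side-relative
#' range standardization (see the methods vignette).
#'
#' @param n grid side.
#' @param b0,b intercept and slope.
#' @param r relative range (fraction of the map side).
#' @param sigma error standard deviation.
#' @param nugget nugget proportion of the error variance.
#' @param seed RNG seed.
#' @param geometry optional precomputed [spatial_sim_geometry()] (reused
#'   across replicates by the harnesses).
#' @return a [spatial_dataset()] with design `(1, x)`; the generating spec
#'   is attached as attribute `"spec"`.
#' @export
simulate_spatial <- function(n = 60, b0 = 0, b = 0, r = 0.03, sigma = 17.1,
                             nugget = 0, seed = NULL, geometry = NULL) {
  if (is.null(geometry)) geometry <- spatial_sim_geometry(n, r, nugget)
  N <- nrow(geometry$coords)
  gam <- with_seed(seed, drop(crossprod(geometry$R, stats::rnorm(N))))
  y <- b0 + b * geometry$x + sigma * gam
  out <- spatial_dataset(geometry$coords, cbind(x = geometry$x), y,
                         names = c("(Intercept)", "lat"))
  attr(out, "spec") <- list(n = n, b0 = b0, b = b, r = r, sigma = sigma,
                            nugget = nugget, seed = seed)
  out
}

#' Simulate the spatiotemporal land-cover-trend design
#'
#' Pixel time series `z_l(t) = c_l t + e_l(t)` with AR(1) errors
#' `e_l(t) = beta e_l(t-1) + d_l(t)` on an `n` x `n` grid; the innovations
#' `d(t)` at each time are spatially correlated (exponential model, unit
#' variance) and independent across times; the AR recursion starts from the
#' stationary distribution. The map splits into 4 x 4 square blocks
#' assigned to four land-cover classes with trends `0, c, 2c, 3c`; each
#' pixel's trend additionally gets local Gaussian noise (sd
#' `trend_noise_sd`). The trend covariate runs from 0 to 1 over the series.
#'
#' @param n grid side (multiple of 4).
#' @param T_ series length.
#' @param beta common AR(1) coefficient.
#' @param r relative range of the innovation spatial correlation.
#' @param c_step class trend step `c`.
#' @param trend_noise_sd sd of the pixel-level trend noise (reference design:
#'   `sqrt(0.16) = 0.4`).
#' @param nugget nugget of the innovation spatial correlation.
#' @param seed RNG seed.
#' @param geometry optional precomputed [spatial_sim_geometry()].
#' @return list: `zmat` (N x T), `coords`, `class` (factor), `X` (intercept
#'   + class dummies), `times` (scaled), `trends` (true per-pixel trends).
#' @export
simulate_spatiotemporal <- function(n = 40, T_ = 30, beta = 0.2, r = 0.03,
                                    c_step = 0, trend_noise_sd = 0.4,
                                    nugget = 0, seed = NULL,
                                    geometry = NULL) {
  stopifnot(n %% 4 == 0, abs(beta) < 1)
  if (is.null(geometry)) geometry <- spatial_sim_geometry(n, r, nugget)
  N <- nrow(geometry$coords)
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  bi <- ceiling(g$row / (n / 4)); bj <- ceiling(g$col / (n / 4))
  cls <- ((bi + bj) %% 4) + 1L
  class_trend <- c(0, 1, 2, 3)[cls] * c_step
  times <- (seq_len(T_) - 1) / (T_ - 1)
  out <- with_seed(seed, {
    trends <- class_trend + stats::rnorm(N, 0, trend_noise_sd)
    innov <- crossprod(geometry$R, matrix(stats::rnorm(N * T_), N, T_))
    eps <- matrix(0, N, T_)
    eps[, 1] <- innov[, 1] / sqrt(1 - beta^2)
    for (t in 2:T_) eps[, t] <- beta * eps[, t - 1] + innov[, t]
    list(trends = trends, eps = eps)
  })
  zmat <- outer(out$trends, times) + out$eps
  X <- stats::model.matrix(~ factor(cls))
  colnames(X) <- c("(Intercept)", paste0("class", 2:4))
  list(zmat = zmat, coords = geometry$coords, class = factor(cls), X = X,
       times = times, trends = out$trends,
       spec = list(n = n, T_ = T_, beta = beta, r = r, c_step = c_step,
                   trend_noise_sd = trend_noise_sd, nugget = nugget,
                   seed = seed))
}

binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 1 / n) / n)

#' Analytic residual/trend correlation table for paired AR(1) series
#'
#' For one series with `beta_l = 0.8` and the other with
#' `beta_k in {-0.4, 0, 0.4, 0.8}`, series lengths `T in {10, 30, 100}` and
#' innovation correlation 0.5: the contemporaneous residual correlation,
#' the LS trend-estimate correlation, and their ratio, all computed
#' analytically from the cross-covariance of the two AR processes.
#'
#' @param beta_l first-series AR coefficient.
#' @param beta_k_grid second-series AR coefficients.
#' @param T_grid series lengths.
#' @param cor_delta innovation correlation.
#' @return data.frame with one row per (beta_k, T).
#' @export
run_table1 <- function(beta_l = 0.8, beta_k_grid = c(-0.4, 0, 0.4, 0.8),
                       T_grid = c(10, 30, 100), cor_delta = 0.5) {
  grid <- expand.grid(T_ = T_grid, beta_k = beta_k_grid)
  grid <- grid[order(match(grid$beta_k, beta_k_grid), grid$T_), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pair <- analytic_pair_covariance(beta_l, grid$beta_k[i], cor_delta,
                                     grid$T_[i])
    ce <- cor_residuals_analytic(pair)
    ct <- cor_trend_analytic(pair)
    data.frame(beta_l = beta_l, beta_k = grid$beta_k[i], T_ = grid$T_[i],
               cor_delta = cor_delta, cor_resid = ce, cor_trend = ct,
               ratio = ct / ce)
  })
  do.call(rbind, rows)
}

## simulate n_pairs paired AR(1) series (vectorized across pairs)
sim_ar1_pairs <- function(n_pairs, beta_l, beta_k, cor_delta, T_) {
  dl <- matrix(stats::rnorm(n_pairs * T_), n_pairs, T_)
  dk <- cor_delta * dl +
    sqrt(1 - cor_delta^2) * matrix(stats::rnorm(n_pairs * T_), n_pairs, T_)
  el <- ek <- matrix(0, n_pairs, T_)
  ## stationary bivariate start
  Om <- matrix(c(1 / (1 - beta_l^2), cor_delta / (1 - beta_l * beta_k),
                 cor_delta / (1 - beta_l * beta_k), 1 / (1 - beta_k^2)), 2)
  Ls <- chol(Om)
  z0 <- matrix(stats::rnorm(2 * n_pairs), n_pairs, 2) %*% Ls
  el[, 1] <- z0[, 1]; ek[, 1] <- z0[, 2]
  for (t in 2:T_) {
    el[, t] <- beta_l * el[, t - 1] + dl[, t]
    ek[, t] <- beta_k * ek[, t - 1] + dk[, t]
  }
  list(el = el, ek = ek)
}

#' Simulated residual/trend correlations for AR(1)-REML pixel fits
#'
#' Simulates pairs of AR(1) series, fits the trend regression with
#' AR(1)-REML (or LS) to every series, and reports per cell the mean
#' correlation of the two residual series and the across-pair correlation
#' of the two trend estimates, with Monte-Carlo standard errors.
#'
#' @param beta_l first-series AR coefficient.
#' @param beta_k_grid,T_grid cell grid.
#' @param cor_delta innovation correlation.
#' @param n_pairs simulated pairs per cell (>= 1000).
#' @param method `"reml"` or `"ls"`.
#' @param seed RNG seed.
#' @return data.frame with one row per cell: `cor_resid`, `cor_trend`,
#'   `ratio` and standard errors.
#' @export
run_table2 <- function(beta_l = 0.8, beta_k_grid = c(-0.4, 0, 0.4, 0.8),
                       T_grid = c(10, 30, 100), cor_delta = 0.5,
                       n_pairs = 5000, method = c("reml", "ls"),
                       seed = NULL) {
  stopifnot(n_pairs >= 1000)
  method <- match.arg(method)
  grid <- expand.grid(T_ = T_grid, beta_k = beta_k_grid)
  grid <- grid[order(match(grid$beta_k, beta_k_grid), grid$T_), ]
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, nrow(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    T_ <- grid$T_[i]; bk <- grid$beta_k[i]
    sims <- with_seed(seeds[i],
                      sim_ar1_pairs(n_pairs, beta_l, bk, cor_delta, T_))
    times <- seq_len(T_)
    fit1 <- fit_pixels(sims$el, times, method)
    fit2 <- fit_pixels(sims$ek, times, method)
    r1 <- fit1$residuals - rowMeans(fit1$residuals)
    r2 <- fit2$residuals - rowMeans(fit2$residuals)
    cr <- rowSums(r1 * r2) / sqrt(rowSums(r1^2) * rowSums(r2^2))
    cor_resid <- mean(cr)
    cor_trend <- stats::cor(fit1$fits$trend, fit2$fits$trend)
    data.frame(beta_l = beta_l, beta_k = bk, T_ = T_, cor_delta = cor_delta,
               cor_resid = cor_resid,
               cor_resid_se = stats::sd(cr) / sqrt(n_pairs),
               cor_trend = cor_trend,
               cor_trend_se = (1 - cor_trend^2) / sqrt(n_pairs),
               ratio = cor_trend / cor_resid, n_pairs = n_pairs)
  })
  do.call(rbind, rows)
}

## build the (fixed-geometry) partition designs for one spatial cell; the
## scheme, whitening and cross-partition correlations depend only on the
## geometry, so they are computed once and reused for every replicate.
spatial_cell_designs <- function(geometry, n_p_list, pair_budget, seed) {
  X <- cbind(`(Intercept)` = 1, lat = geometry$x)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                      length(n_p_list)))
  lapply(seq_along(n_p_list), function(k) {
    pgls_design(geometry$coords, X, geometry$model, n_p = n_p_list[k],
                reduced = list(drop = "lat"), pair_budget = pair_budget,
                seed = seeds[k])
  })
}

#' Power of the partitioned LRT versus the number of partitions
#'
#' Simulates the spatial regression design with a fixed slope, tests
#' `H0: b = 0` at level `alpha` for each number of partitions (full-data
#' F-test for `n_p = 1`, combined LRT otherwise), and reports rejection
#' proportions with binomial standard errors. By default every replicate
#' dataset is partitioned afresh, as in the reference study; with
#' `repartition = FALSE` one scheme per cell is reused across replicates
#' (faster, but the scheme-level variability then shifts all replicates of
#' a cell together).
#'
#' @param n_p_list numbers of partitions.
#' @param r_list relative ranges.
#' @param n_reps simulation replicates per cell.
#' @param b true slope.
#' @param sigma error standard deviation (see [simulate_spatial()]).
#' @param alpha significance level.
#' @param n grid side.
#' @param pair_budget cross-partition pair budget.
#' @param repartition draw a new partition scheme for every replicate.
#' @param seed RNG seed.
#' @return data.frame: one row per (r, n_p) with `reject`, `se`.
#' @export
run_table3 <- function(n_p_list = c(1, 2, 4, 8, 16), r_list = c(0.03, 0.1),
                       n_reps = 500, b = 10, sigma = 17.1, alpha = 0.05,
                       n = 60, pair_budget = 15, repartition = TRUE,
                       seed = NULL) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                      2 * length(r_list)))
  out <- list()
  for (ri in seq_along(r_list)) {
    r <- r_list[ri]
    geom <- spatial_sim_geometry(n, r)
    X <- cbind(`(Intercept)` = 1, lat = geom$x)
    designs <- spatial_cell_designs(geom, n_p_list, pair_budget,
                                    seeds[2 * ri - 1])
    rej <- matrix(0L, n_reps, length(n_p_list))
    with_seed(seeds[2 * ri], {
      N <- nrow(geom$coords)
      for (rep in seq_len(n_reps)) {
        y <- b * geom$x + sigma * drop(crossprod(geom$R, stats::rnorm(N)))
        for (k in seq_along(n_p_list)) {
          des <- if (n_p_list[k] > 1 && repartition)
            pgls_design(geom$coords, X, geom$model, n_p = n_p_list[k],
                        reduced = list(drop = "lat"),
                        pair_budget = pair_budget,
                        seed = sample.int(.Machine$integer.max, 1))
          else designs[[k]]
          pg <- pgls_apply(des, y)
          pval <- if (n_p_list[k] == 1) pg$p_f[1] else combined_lrt(pg)$p_value
          rej[rep, k] <- pval <= alpha
        }
      }
    })
    pr <- colMeans(rej)
    out[[ri]] <- data.frame(r = r, n_p = n_p_list, reject = pr,
                            se = binom_se(pr, n_reps), n_reps = n_reps,
                            b = b, alpha = alpha)
  }
  do.call(rbind, out)
}

#' Type-I error and power curves for all combining methods (spatial design)
#'
#' For each slope in `b_grid` and each range in `r_list`, simulates the
#' spatial design and tests `H0: b = 0` with: the full-data GLS F-test
#' (`gls`), the partitioned F (`part_f`, parametric bootstrap), LRT
#' (`part_lrt`) and t (`part_t`) combinations, Hochberg- and FDR-adjusted
#' minimum per-partition p-values (`hochberg`, `fdr`) and one random
#' partition (`single`).
#'
#' @param b_grid slopes (0 = null).
#' @param r_list relative ranges.
#' @param alpha_list significance levels.
#' @param n_reps replicates per cell.
#' @param sigma error standard deviation (see [simulate_spatial()]).
#' @param n grid side.
#' @param n_p number of partitions for the partition methods.
#' @param n_boot bootstrap draws for the combined F (the bootstrap null
#'   sample depends only on the cell geometry and is shared across
#'   replicates).
#' @param pair_budget cross-partition pair budget.
#' @param seed RNG seed.
#' @return data.frame: one row per (r, b, alpha, method).
#' @export
run_fig1 <- function(b_grid = seq(0, 20, 2), r_list = c(0.03, 0.1),
                     alpha_list = c(0.05, 0.01), n_reps = 500, sigma = 17.1,
                     n = 60, n_p = 8, n_boot = 1e5, pair_budget = 15,
                     seed = NULL) {
  methods <- c("gls", "part_f", "part_lrt", "part_t", "hochberg", "fdr",
               "single")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                      3 * length(r_list)))
  out <- list()
  for (ri in seq_along(r_list)) {
    r <- r_list[ri]
    geom <- spatial_sim_geometry(n, r)
    designs <- spatial_cell_designs(geom, c(1, n_p), pair_budget,
                                    seeds[3 * ri - 2])
    N <- nrow(geom$coords)
    ## bootstrap null F sample: fixed by the geometry, shared across reps
    pg_probe <- pgls_apply(designs[[2]],
                           drop(crossprod(geom$R, with_seed(
                             seeds[3 * ri - 1], stats::rnorm(N)))))
    fboot <- with_seed(seeds[3 * ri - 1],
                       boot_f_draws(pg_probe, n_boot)$F)
    for (b in b_grid) {
      pv <- with_seed(seeds[3 * ri] + round(b * 1000), {
        sapply(seq_len(n_reps), function(rep) {
          y <- b * geom$x + sigma * drop(crossprod(geom$R, stats::rnorm(N)))
          pg1 <- pgls_apply(designs[[1]], y)
          pg <- pgls_apply(designs[[2]], y)
          F_obs <- (sum(pg$SSR) / (pg$n_p * pg$df1)) /
            (sum(pg$SSE) / sum(pg$df2))
          base <- comparison_baselines(pg$p_f, seed = NULL)
          c(gls = pg1$p_f[1],
            part_f = mean(fboot >= F_obs),
            part_lrt = combined_lrt(pg)$p_value,
            part_t = combined_t(pg, coef = "lat")$p_value,
            hochberg = base$hochberg, fdr = base$fdr, single = base$single)
        })
      })
      for (alpha in alpha_list) {
        pr <- rowMeans(pv <= alpha)
        out[[length(out) + 1L]] <-
          data.frame(r = r, b = b, alpha = alpha, method = methods,
                     reject = unname(pr[methods]),
                     se = binom_se(unname(pr[methods]), n_reps),
                     n_reps = n_reps)
      }
    }
  }
  do.call(rbind, out)
}

#' Repartitioning variability of the combined LRT p-value
#'
#' Fixes one simulated dataset and reruns the partitioned analysis with
#' different random partition schemes, returning the distribution of
#' combined-LRT p-values (whose spread is induced solely by the
#' partitioning).
#'
#' @param data a [spatial_dataset()] (e.g. from [simulate_spatial()]); its
#'   attached spec supplies the correlation model unless `model` is given.
#' @param model optional [cor_model()].
#' @param n_repartitions number of partition schemes.
#' @param n_p partitions per scheme.
#' @param pair_budget cross-partition pair budget.
#' @param seed RNG seed.
#' @return list: `p_values`, `median`, `iqr`, `range`.
#' @export
run_fig2 <- function(data, model = NULL, n_repartitions = 100, n_p = 8,
                     pair_budget = 15, seed = NULL) {
  if (is.null(model)) {
    spec <- attr(data, "spec")
    if (is.null(spec)) stop("supply model= for datasets without a spec")
    model <- cor_model("exponential", range = spec$r, nugget = spec$nugget)
  }
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_repartitions))
  pv <- vapply(seeds, function(s) {
    pg <- partition_gls(data, model, reduced = list(drop = "lat"), n_p = n_p,
                        pair_budget = pair_budget, seed = s)
    combined_lrt(pg)$p_value
  }, numeric(1))
  list(p_values = pv, median = stats::median(pv), iqr = stats::IQR(pv),
       range = range(pv))
}

#' Type-I error and power for the spatiotemporal land-cover design
#'
#' For each trend step `c` and range `r`, simulates the land-cover design,
#' runs the spatiotemporal pipeline (AR(1)-REML pixel fits, range from
#' residual correlations, partitioned GLS with per-partition ML nugget),
#' and tests (a) no differences in trends among land-cover classes and
#' (b) no overall trend, using the combined LRT (`part`), Hochberg/FDR
#' adjusted per-partition tests and a random single partition. An optional
#' full-map GLS (`gls`, with ML nugget) is available for small maps.
#'
#' @param c_grid trend steps (0 = null).
#' @param r_list relative ranges.
#' @param n_reps replicates per cell.
#' @param n grid side (multiple of 4).
#' @param T_ series length.
#' @param beta AR(1) coefficient of the simulated errors.
#' @param n_p number of partitions.
#' @param alpha significance level.
#' @param n_pairs residual-correlation pairs for the range fit.
#' @param include_gls also run the full-map GLS (costly).
#' @param seed RNG seed.
#' @return data.frame: one row per (r, c, hypothesis, method).
#' @export
run_fig3 <- function(c_grid = seq(0, 0.2, 0.04), r_list = c(0.03, 0.1),
                     n_reps = 500, n = 40, T_ = 30, beta = 0.2, n_p = 8,
                     alpha = 0.05, n_pairs = 2000, include_gls = FALSE,
                     seed = NULL) {
  out <- list()
  hyps <- c("among_class", "overall_trend")
  methods <- c(if (include_gls) "gls", "part", "hochberg", "fdr", "single")
  seeds0 <- with_seed(seed, sample.int(.Machine$integer.max,
                                       length(r_list) * length(c_grid)))
  cell <- 0L
  for (r in r_list) {
    geom <- spatial_sim_geometry(n, r)
    for (cs in c_grid) {
      cell <- cell + 1L
      rs <- with_seed(seeds0[cell],
                      sample.int(.Machine$integer.max, n_reps))
      rej <- array(0, c(n_reps, length(hyps), length(methods)),
                   dimnames = list(NULL, hyps, methods))
      for (rep in seq_len(n_reps)) {
        sim <- simulate_spatiotemporal(n, T_, beta, r, c_step = cs,
                                       seed = rs[rep], geometry = geom)
        res <- st_cell_tests(sim, n_p = n_p, n_pairs = n_pairs,
                             include_gls = include_gls,
                             seed = rs[rep] %% 10000L + 1L)
        for (h in hyps) for (m in methods)
          rej[rep, h, m] <- res[[h]][[m]] <= alpha
      }
      for (h in hyps) for (m in methods) {
        pr <- mean(rej[, h, m])
        out[[length(out) + 1L]] <-
          data.frame(r = r, c_step = cs, hypothesis = h, method = m,
                     reject = pr, se = binom_se(pr, n_reps),
                     n_reps = n_reps, alpha = alpha)
      }
    }
  }
  do.call(rbind, out)
}

## both hypothesis tests for one simulated spatiotemporal dataset,
## sharing the pixel fits and range model between them
st_cell_tests <- function(sim, n_p, n_pairs, include_gls = FALSE,
                          seed = NULL) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 4L))
  pf <- fit_pixels(sim$zmat, sim$times, "reml")
  pc <- residual_cor_pairs(pf$residuals, sim$coords, n_pairs,
                           seed = seeds[1])
  rm_ <- estimate_range_model(pc$cor, pc$d, "exponential")
  data_cls <- spatial_dataset(sim$coords, sim$X, pf$fits$trend)
  pg_cls <- partition_gls(data_cls, rm_,
                          reduced = list(drop = paste0("class", 2:4)),
                          n_p = n_p, seed = seeds[2], estimate_nugget = TRUE)
  base_cls <- comparison_baselines(pg_cls$p_f, seed = seeds[3])
  data_ov <- spatial_dataset(sim$coords,
                             matrix(1, nrow(sim$zmat), 1,
                                    dimnames = list(NULL, "(Intercept)")),
                             pf$fits$trend)
  pg_ov <- partition_gls(data_ov, rm_,
                         reduced = list(drop = "(Intercept)"),
                         n_p = n_p, seed = seeds[2], estimate_nugget = TRUE)
  base_ov <- comparison_baselines(pg_ov$p_f, seed = seeds[4])
  res <- list(
    among_class = list(part = combined_lrt(pg_cls)$p_value,
                       hochberg = base_cls$hochberg, fdr = base_cls$fdr,
                       single = base_cls$single),
    overall_trend = list(part = combined_lrt(pg_ov)$p_value,
                         hochberg = base_ov$hochberg, fdr = base_ov$fdr,
                         single = base_ov$single))
  if (include_gls) {
    est_cls <- estimate_nugget_ml(data_cls$y, data_cls$X, data_cls$coords,
                                  rm_)
    red_cls <- gls_fit(data_cls$X[, 1, drop = FALSE], data_cls$y,
                       D = est_cls$D)
    res$among_class$gls <- f_test(est_cls$fit, red_cls)$p_value
    est_ov <- estimate_nugget_ml(data_ov$y, data_ov$X, data_ov$coords, rm_)
    red_ov <- gls_fit(matrix(numeric(0), nrow(data_ov$X), 0), data_ov$y,
                      D = est_ov$D)
    res$overall_trend$gls <- f_test(est_ov$fit, red_ov)$p_value
  }
  res
}
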