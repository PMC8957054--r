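#' Least-squares trend fit for one pixel time series
#'
#' Ordinary regression of `z` on an intercept and time. The trend estimate
#' becomes the response of the later spatial GLS stage; the residuals feed
#' the spatial correlation-range estimation.
#'
#' @param z numeric series (length T >= 3).
#' @param times time covariate (default `1:T`).
#' @return list of class `"pixel_fit"`: `intercept`, `trend`, `beta` (0 for
#'   LS), `sigma2`, `residuals`, `method`.
#' @export
fit_pixel_ls <- function(z, times = seq_along(z)) {
  T_ <- length(z)
  stopifnot(T_ >= 3, length(times) == T_, all(is.finite(z)))
  if (stats::sd(times) == 0) stop("time covariate is constant")
  tc <- times - mean(times)
  slope <- sum(tc * z) / sum(tc^2)
  intercept <- mean(z) - slope * mean(times)
  res <- z - intercept - slope * times
  structure(list(intercept = intercept, trend = slope, beta = 0,
                 sigma2 = sum(res^2) / (T_ - 2), residuals = res,
                 method = "LS"),
            class = "pixel_fit")
}

## negative restricted log-likelihood profile for the AR(1) regression,
## via the O(T) analytic whitening z*_1 = sqrt(1-b^2) z_1, z*_t = z_t - b z_{t-1}
ar1_reml_nll <- function(b, z, times) {
  T_ <- length(z)
  w1 <- sqrt(1 - b^2)
  zs <- c(w1 * z[1], z[-1] - b * z[-T_])
  os <- c(w1, rep(1 - b, T_ - 1))
  ts_ <- c(w1 * times[1], times[-1] - b * times[-T_])
  m11 <- sum(os^2); m12 <- sum(os * ts_); m22 <- sum(ts_^2)
  v1 <- sum(os * zs); v2 <- sum(ts_ * zs)
  det_m <- m11 * m22 - m12^2
  if (det_m <= 0) return(1e10)
  b2 <- (m11 * v2 - m12 * v1) / det_m
  b1 <- (v1 - m12 * b2) / m11
  sse <- sum((zs - b1 * os - b2 * ts_)^2)
  s2 <- sse / (T_ - 2)
  0.5 * ((T_ - 2) * log(s2) - log(1 - b^2) + log(det_m))
}

#' AR(1)-REML trend fit for one pixel time series
#'
#' Regression of `z` on intercept and time with AR(1) errors
#' `e(t) = beta e(t-1) + d(t)`: the autocorrelation `beta` maximizes the
#' restricted likelihood (innovation variance profiled out) by bounded
#' scalar optimization on `(-1, 1)`; the trend is the GLS estimate at the
#' optimum. The likelihood uses the exact stationary AR(1) correlation
#' (including the first observation), evaluated in O(T) by analytic
#' whitening.
#'
#' @param z numeric series (length T >= 5).
#' @param times time covariate.
#' @param bound open-interval bound for `|beta|`.
#' @return a `"pixel_fit"` (see [fit_pixel_ls()]) with `beta` the REML
#'   estimate, `sigma2` the REML innovation variance and raw residuals
#'   `z - a - c t`.
#' @export
fit_pixel_ar1_reml <- function(z, times = seq_along(z), bound = 1 - 1e-6) {
  T_ <- length(z)
  stopifnot(T_ >= 5, length(times) == T_, all(is.finite(z)))
  if (stats::sd(times) == 0) stop("time covariate is constant")
  opt <- stats::optimize(ar1_reml_nll, c(-bound, bound), z = z, times = times,
                         tol = 1e-8)
  b <- opt$minimum
  ## GLS coefficients at beta-hat (same whitening as the profile)
  w1 <- sqrt(1 - b^2)
  zs <- c(w1 * z[1], z[-1] - b * z[-T_])
  os <- c(w1, rep(1 - b, T_ - 1))
  ts_ <- c(w1 * times[1], times[-1] - b * times[-T_])
  m11 <- sum(os^2); m12 <- sum(os * ts_); m22 <- sum(ts_^2)
  v1 <- sum(os * zs); v2 <- sum(ts_ * zs)
  det_m <- m11 * m22 - m12^2
  b2 <- (m11 * v2 - m12 * v1) / det_m
  b1 <- (v1 - m12 * b2) / m11
  sse <- sum((zs - b1 * os - b2 * ts_)^2)
  structure(list(intercept = b1, trend = b2, beta = b,
                 sigma2 = sse / (T_ - 2),
                 residuals = z - b1 - b2 * times,
                 logLik = -opt$objective, method = "AR1-REML"),
            class = "pixel_fit")
}

#' @export
print.pixel_fit <- function(x, ...) {
  cat(sprintf("%s pixel fit: trend = %.5g, beta = %.4g, sigma2 = %.5g\n",
              x$method, x$trend, x$beta, x$sigma2))
  invisible(x)
}

#' Fit trend models to every pixel of a pixel-by-time matrix
#'
#' @param zmat N x T matrix (rows = pixels).
#' @param times time covariate shared by all pixels.
#' @param method `"reml"` (AR(1) errors) or `"ls"`.
#' @return list with data.frame `fits` (`intercept`, `trend`, `beta`,
#'   `sigma2`) and matrix `residuals` (N x T).
#' @export
fit_pixels <- function(zmat, times = seq_len(ncol(zmat)),
                       method = c("reml", "ls")) {
  method <- match.arg(method)
  zmat <- as.matrix(zmat)
  f <- if (method == "reml") fit_pixel_ar1_reml else fit_pixel_ls
  out <- apply(zmat, 1L, function(z) {
    ft <- f(z, times)
    c(ft$intercept, ft$trend, ft$beta, ft$sigma2, ft$residuals)
  })
  list(fits = data.frame(intercept = out[1, ], trend = out[2, ],
                         beta = out[3, ], sigma2 = out[4, ]),
       residuals = t(out[-(1:4), , drop = FALSE]),
       method = method, times = times)
}

## (I - beta Psi)^{-1} for the T x T backward-shift matrix Psi:
## lower-triangular with entries beta^(t-s)
ar1_propagator <- function(beta, T_) {
  idx <- outer(seq_len(T_), seq_len(T_), "-")
  M <- ifelse(idx >= 0, beta^idx, 0)
  matrix(M, T_, T_)
}

#' Analytic cross-covariance of two AR(1) error series
#'
#' For pixels l, k with AR coefficients `beta_l`, `beta_k` whose
#' contemporaneous innovations have correlation `cor_delta`, the T x T
#' matrix `W` of covariances `cov[e_l(t), e_k(s)]` under stationary
#' initialization is
#' `W = cor_delta * (I - beta_l Psi)^{-1} Delta ((I - beta_k Psi)^{-1})'`
#' with `Psi` the backward shift and `Delta` diagonal: its first element is
#' the stationary cross-covariance with `cor_delta` factored out,
#' `sigma2/(1 - beta_l beta_k)`, the rest `sigma2`.
#'
#' @param beta_l,beta_k AR(1) coefficients, `|beta| < 1`.
#' @param cor_delta innovation correlation (1 for a self pair).
#' @param T_ series length.
#' @param sigma2 innovation variance.
#' @return list of class `"ar_pair"` with `W` and the inputs.
#' @export
analytic_pair_covariance <- function(beta_l, beta_k, cor_delta, T_,
                                     sigma2 = 1) {
  if (abs(beta_l) >= 1 || abs(beta_k) >= 1)
    stop("nonstationary AR(1): |beta| must be < 1")
  A_l <- ar1_propagator(beta_l, T_)
  A_k <- ar1_propagator(beta_k, T_)
  Delta <- diag(c(sigma2 / (1 - beta_l * beta_k), rep(sigma2, T_ - 1)))
  W <- cor_delta * A_l %*% Delta %*% t(A_k)
  structure(list(W = W, beta_l = beta_l, beta_k = beta_k,
                 cor_delta = cor_delta, T_ = T_, sigma2 = sigma2),
            class = "ar_pair")
}

#' Contemporaneous correlation of two AR(1) error series at stationarity
#'
#' From the stationary bivariate covariance (the fixed point of the joint
#' AR recursion): `cor[e_l(t), e_k(t)] =
#' cor_delta sqrt((1-beta_l^2)(1-beta_k^2)) / (1 - beta_l beta_k)`.
#' Equals `cor_delta` when `beta_l = beta_k`.
#'
#' @param pair an `"ar_pair"` from [analytic_pair_covariance()].
#' @return scalar correlation.
#' @export
cor_residuals_analytic <- function(pair) {
  with(pair, cor_delta * sqrt((1 - beta_l^2) * (1 - beta_k^2)) /
         (1 - beta_l * beta_k))
}

#' Analytic correlation of least-squares trend estimates of two pixels
#'
#' With `K` the trend row of `(J'J)^{-1}J'` for the LS design
#' `J = [1, t]`, the trend estimates have correlation
#' `K W_lk K' / sqrt((K W_ll K')(K W_kk K'))`, the self-pair covariances
#' `W_ll`, `W_kk` taken at innovation correlation 1.
#'
#' @param pair an `"ar_pair"`.
#' @return scalar correlation.
#' @export
cor_trend_analytic <- function(pair) {
  T_ <- pair$T_
  J <- cbind(1, seq_len(T_))
  K <- solve(crossprod(J), t(J))[2L, ]
  W_ll <- analytic_pair_covariance(pair$beta_l, pair$beta_l, 1, T_,
                                   pair$sigma2)$W
  W_kk <- analytic_pair_covariance(pair$beta_k, pair$beta_k, 1, T_,
                                   pair$sigma2)$W
  num <- drop(K %*% pair$W %*% K)
  den <- sqrt(drop(K %*% W_ll %*% K) * drop(K %*% W_kk %*% K))
  num / den
}

#' Estimate the spatial correlation-range model from residual correlations
#'
#' Nonlinear least-squares fit of `v(d) = exp(-(d/r)^g)` (shape `g` fixed at
#' 1 for the exponential family) to sampled pairwise correlations of
#' time-series residuals against distance. For large pixel sets the fit has
#' negligible parameter uncertainty, so the fitted model is treated as known
#' downstream; the nugget is not fitted here (it is estimated later, by ML,
#' inside the spatial GLS).
#'
#' @param cors pairwise residual correlations.
#' @param dists matching distances.
#' @param family `"exponential"` or `"exponential_power"` (fits `g` too).
#' @return a [cor_model()] with attributes `rss` (residual sum of squares)
#'   and `n_pairs`.
#' @export
estimate_range_model <- function(cors, dists,
                                 family = c("exponential",
                                            "exponential_power")) {
  family <- match.arg(family)
  if (length(cors) != length(dists))
    stop("cors and dists must have the same length")
  ok <- is.finite(cors) & is.finite(dists) & dists > 0
  cors <- cors[ok]; dists <- dists[ok]
  if (length(cors) < 20) stop("need at least 20 pixel pairs to fit the range")
  dmax <- max(dists)
  if (max(cors) < 0.01) {
    warning("all residual correlations are near zero; range set to the lower boundary")
    m <- cor_model(family, range = 1e-6 * dmax, shape = 1)
    attr(m, "rss") <- sum(cors^2); attr(m, "n_pairs") <- length(cors)
    return(m)
  }
  df <- data.frame(v = cors, d = dists)
  r0 <- stats::median(dists) / 2
  fit <- tryCatch({
    if (family == "exponential")
      stats::nls(v ~ exp(-(d / r)), data = df, start = list(r = r0),
                 algorithm = "port",
                 lower = c(r = 1e-8 * dmax), upper = c(r = 100 * dmax))
    else
      stats::nls(v ~ exp(-(d / r)^g), data = df,
                 start = list(r = r0, g = 1), algorithm = "port",
                 lower = c(r = 1e-8 * dmax, g = 0.05),
                 upper = c(r = 100 * dmax, g = 5))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    ## direct least-squares fallback on log-range scale
    obj <- function(par) {
      g <- if (family == "exponential") 1 else exp(par[2])
      sum((cors - exp(-(dists / exp(par[1]))^g))^2)
    }
    par0 <- if (family == "exponential") log(r0) else c(log(r0), 0)
    op <- stats::optim(par0, obj, method = "BFGS")
    if (op$convergence != 0)
      stop("range-model fit did not converge; try family = 'exponential' (g = 1)")
    r_hat <- exp(op$par[1])
    g_hat <- if (family == "exponential") 1 else exp(op$par[2])
    rss <- op$value
  } else {
    cf <- stats::coef(fit)
    r_hat <- cf[["r"]]
    g_hat <- if (family == "exponential") 1 else cf[["g"]]
    rss <- sum(stats::resid(fit)^2)
  }
  m <- cor_model(family, range = r_hat, shape = g_hat)
  attr(m, "rss") <- rss
  attr(m, "n_pairs") <- length(cors)
  m
}

#' Sample pixel pairs and compute residual correlations vs distance
#'
#' @param residuals N x T residual matrix from [fit_pixels()].
#' @param coords N x 2 coordinates.
#' @param n_pairs number of random pairs (default 2000).
#' @param seed RNG seed for the pair subsample.
#' @return data.frame with `d` and `cor` per sampled pair.
#' @export
residual_cor_pairs <- function(residuals, coords, n_pairs = 2000,
                               seed = NULL) {
  N <- nrow(residuals)
  pr <- with_seed(seed, cbind(sample.int(N, n_pairs, replace = TRUE),
                              sample.int(N, n_pairs, replace = TRUE)))
  pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
  rc <- residuals - rowMeans(residuals)
  ss <- sqrt(rowSums(rc^2))
  cors <- rowSums(rc[pr[, 1], , drop = FALSE] * rc[pr[, 2], , drop = FALSE]) /
    (ss[pr[, 1]] * ss[pr[, 2]])
  d <- sqrt(rowSums((coords[pr[, 1], , drop = FALSE] -
                       coords[pr[, 2], , drop = FALSE])^2))
  data.frame(d = d, cor = cors)
}

#' Maximum-likelihood nugget estimation inside a spatial GLS
#'
#' With the range model fixed (from the time-series residuals), profiles
#' the Gaussian log-likelihood of the GLS regression over the nugget in
#' `[0, 1)` by bounded scalar optimization, and returns the GLS fit at the
#' optimum.
#'
#' @param y response (e.g. per-pixel trend estimates).
#' @param X design matrix.
#' @param coords coordinates.
#' @param range_model a [cor_model()]; its nugget entry is ignored.
#' @param upper upper bound of the nugget search.
#' @return list: `nugget`, `model` (updated [cor_model()]), `D` (whitening
#'   at the optimum), `fit` ([gls_fit()]), `logLik`.
#' @export
estimate_nugget_ml <- function(y, X, coords, range_model, upper = 1 - 1e-6) {
  X <- as.matrix(X)
  N <- length(y)
  d <- cross_dist(coords)
  base <- exp(-(d / range_model$range)^range_model$shape)
  diag(base) <- 1
  nll <- function(nug) {
    C <- (1 - nug) * base
    diag(C) <- 1
    R <- tryCatch(chol_jitter(C), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    W <- forwardsolve(t(R), cbind(X, y))
    res <- stats::lm.fit(W[, -ncol(W), drop = FALSE], W[, ncol(W)])$residuals
    sse <- sum(res^2)
    0.5 * (N * log(sse / N) + 2 * sum(log(diag(R))))
  }
  opt <- stats::optimize(nll, c(0, upper), tol = 1e-5)
  nug <- opt$minimum
  if (nll(0) <= opt$objective + 1e-8) nug <- 0   # flat toward the boundary
  model <- range_model
  model$nugget <- nug
  C <- (1 - nug) * base
  diag(C) <- 1
  D <- whiten(C)
  fit <- gls_fit(X, y, D = D)
  list(nugget = nug, model = model, D = D, fit = fit,
       logLik = -opt$objective)
}

#' Spatiotemporal partitioned-GLS pipeline
#'
#' Full chain for trend analysis of a pixel-by-time matrix: (1) fit a trend
#' model (AR(1)-REML or LS) to every pixel; (2) estimate the spatial
#' correlation range from the correlations of residual time series over a
#' random subset of pixel pairs; (3) run the partitioned GLS of the trend
#' estimates on the pixel-level predictors, estimating the nugget per
#' partition by ML; (4) combine the per-partition tests.
#'
#' @param zmat N x T matrix of observations (rows = pixels).
#' @param coords N x 2 pixel coordinates.
#' @param X N x p spatial design matrix (intercept added if missing).
#' @param times time covariate (default scaled to `[0, 1]`).
#' @param reduced reduced-model specification for the test (see
#'   [pgls_design()]).
#' @param method time-series model, `"reml"` or `"ls"`.
#' @param family correlation family for the range fit.
#' @param n_p number of partitions.
#' @param n_pairs residual-correlation pairs for the range fit.
#' @param pair_budget cross-partition pair budget.
#' @param seed RNG seed (pair sampling, partitioning).
#' @param pixel_fits,range_model optional precomputed stage outputs (from a
#'   previous call), to rerun only the spatial stage.
#' @return list of class `"st_gls"`: `pixel_fits`, `range_model`, `pg`
#'   (the [partition_gls()] object), `lrt` (combined LRT), `nuggets`.
#' @export
spatiotemporal_gls <- function(zmat, coords, X, times = NULL, reduced = NULL,
                               method = c("reml", "ls"),
                               family = "exponential", n_p = 8,
                               n_pairs = 2000, pair_budget = NULL,
                               seed = NULL, pixel_fits = NULL,
                               range_model = NULL) {
  method <- match.arg(method)
  zmat <- as.matrix(zmat)
  T_ <- ncol(zmat)
  if (is.null(times)) times <- (seq_len(T_) - 1) / (T_ - 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2L))
  if (is.null(pixel_fits)) pixel_fits <- fit_pixels(zmat, times, method)
  if (is.null(range_model)) {
    pc <- residual_cor_pairs(pixel_fits$residuals, coords, n_pairs,
                             seed = seeds[1])
    range_model <- estimate_range_model(pc$cor, pc$d, family)
  }
  data <- spatial_dataset(coords, X, pixel_fits$fits$trend)
  pg <- partition_gls(data, range_model, reduced = reduced, n_p = n_p,
                      pair_budget = pair_budget, seed = seeds[2],
                      estimate_nugget = TRUE)
  structure(list(pixel_fits = pixel_fits$fits, range_model = range_model,
                 pg = pg, lrt = combined_lrt(pg), nuggets = pg$nuggets,
                 method = method),
            class = "st_gls")
}

#' @export
print.st_gls <- function(x, ...) {
  cat(sprintf("Spatiotemporal partitioned GLS (%s pixel fits)\n", x$method))
  print(x$range_model)
  cat(sprintf("nugget estimates: %s\n",
              paste(sprintf("%.3f", x$nuggets), collapse = ", ")))
  print(x$lrt)
  invisible(x)
}
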