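#' Correlation matrix of the Gaussian components behind the summed SSR
#'
#' Each partition's SSR statistic (on the chi-square scale) is a sum of
#' `df1` squared independent unit Gaussians. Across partitions `i != j`,
#' every pair of components has correlation `sqrt(rho_ij / df1)`, which
#' reproduces `cor[SSR_i, SSR_j] = rho_ij`. The summed statistic is then
#' distributed as the quadratic form `G'G` with `G ~ N(0, P)`, i.e. a
#' weighted sum of chi-square(1) variables with weights the eigenvalues
#' of `P`.
#'
#' @param rho scalar (used for all pairs) or `n_p` x `n_p` matrix of
#'   SSR correlations; values must be in `[0, 1]` (negatives are clipped
#'   to 0 with a message).
#' @param n_p number of partitions.
#' @param df1 numerator degrees of freedom.
#' @return list with the `(n_p*df1)` square matrix `P` and its eigenvalues
#'   (small negatives from roundoff zeroed).
#' @export
build_P <- function(rho, n_p, df1) {
  if (is.matrix(rho)) {
    stopifnot(nrow(rho) == n_p, ncol(rho) == n_p)
    rho_m <- rho
  } else {
    stopifnot(length(rho) == 1L)
    rho_m <- matrix(rho, n_p, n_p)
  }
  diag(rho_m) <- 1
  if (any(rho_m > 1 + 1e-8)) stop("rho values above 1")
  rho_m <- clip_rho(rho_m)
  dim_ <- n_p * df1
  ## the exchangeable assignment sqrt(rho/df1) to every cross-partition
  ## component pair reproduces cor[SSR_i, SSR_j] = rho but is only positive
  ## semidefinite while rho <= 1/df1; beyond that bound the diagonal
  ## pairing sqrt(rho) * I (same implied SSR covariances) is used instead
  exch <- df1 == 1 || max(rho_m[upper.tri(rho_m)], 0) * df1 <= 1
  if (!exch)
    pg_log("rho * df1 > 1: using diagonal component pairing for P")
  P <- matrix(0, dim_, dim_)
  blk <- function(i) ((i - 1) * df1 + 1):(i * df1)
  for (i in seq_len(n_p)) for (j in seq_len(n_p)) {
    P[blk(i), blk(j)] <- if (i == j) diag(df1)
      else if (exch) matrix(sqrt(rho_m[i, j] / df1), df1, df1)
      else sqrt(rho_m[i, j]) * diag(df1)
  }
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("P is not positive semidefinite (smallest eigenvalue ",
         format(min(ev)), ")")
  ev[ev < 0] <- 0
  list(P = P, eigenvalues = ev)
}

#' Upper tail of a weighted sum of chi-square(1) variables
#'
#' `Pr[sum_k lambda_k chi2_1 > q]`, the distribution of a quadratic form in
#' Gaussian variables, computed by Imhof-type numerical inversion of the
#' characteristic function; falls back to Monte Carlo (10^6 draws, with a
#' message) if the inversion fails.
#'
#' @param q observed value (>= 0).
#' @param lambda eigenvalue weights (or a list from [build_P()]).
#' @param tol absolute tolerance of the inversion.
#' @return tail probability in `[0, 1]`.
#' @export
quadform_tail <- function(q, lambda, tol = 1e-6) {
  if (is.list(lambda)) lambda <- lambda$eigenvalues
  lambda <- lambda[lambda > 1e-12]
  if (length(lambda) == 0L) stop("no positive eigenvalue weights")
  if (q <= 0) return(1)
  ## deep tail: Q <= max(lambda) * chisq(K) gives an upper bound on the
  ## tail; when that bound is below 1e-12 the inversion integrand is
  ## violently oscillatory while the answer is indistinguishable from the
  ## bound at any stated tolerance, so return the bound.
  ub <- stats::pchisq(q / max(lambda), length(lambda), lower.tail = FALSE)
  if (ub < 1e-8) return(ub)
  if (length(lambda) == 1L)             # exact: scaled chi-square(1)
    return(stats::pchisq(q / lambda, 1, lower.tail = FALSE))
  if (length(lambda) == 2L) {
    ## exact smooth form: P = (1/2pi) Int exp(-q / (2 (l1 c^2 + l2 s^2)))
    f2 <- function(th)
      exp(-q / (2 * (lambda[1] * cos(th)^2 + lambda[2] * sin(th)^2)))
    return(min(max(2 / pi * stats::integrate(f2, 0, pi / 2,
                                             abs.tol = tol * 1e-2)$value,
                   0), 1))
  }
  integrand <- function(u) {
    lu <- outer(lambda, u)
    theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
    lrho <- 0.25 * colSums(log1p(lu^2))
    out <- sin(theta) / (u * exp(lrho))
    out[u == 0] <- 0.5 * (sum(lambda) - q)
    out
  }
  ## truncate the inversion integral where the envelope
  ## 1/(u prod(1+l^2u^2)^{1/4}) <= u^{-1-K/2}/prod(sqrt(l)) makes the
  ## remaining tail negligible
  K <- length(lambda)
  U <- (2 / (K * pi * (tol * 1e-1) * prod(sqrt(lambda))))^(2 / K)
  imhof <- function(rel.tol, subdivisions)
    0.5 + stats::integrate(integrand, 0, U, abs.tol = tol * 1e-2,
                           rel.tol = rel.tol,
                           subdivisions = subdivisions)$value / pi
  val <- tryCatch(imhof(1e-5, 10000L), error = function(e1)
    tryCatch(imhof(1e-3, 50000L), error = function(e2) {
      pg_log("quadratic-form inversion failed (", conditionMessage(e2),
             "); falling back to 1e6-draw Monte Carlo")
      n <- 1e6L
      draws <- colSums(lambda * matrix(stats::rchisq(n * length(lambda), 1),
                                       length(lambda), n))
      mean(draws > q)
    }))
  min(max(val, 0), 1)
}

combined_result <- function(statistic, p_value, pg, method, df1, df2, ...) {
  structure(list(statistic = statistic, p_value = min(max(p_value, 0), 1),
                 n_p = pg$n_p, df1 = df1, df2 = df2, method = method,
                 rho_ssr = pg$cross$rho_ssr_mean,
                 rho_sse = pg$cross$rho_sse_mean, ...),
            class = c("combined_test", "pg_test"))
}

#' Combined likelihood-ratio test across partitions
#'
#' Sums the per-partition LRT statistics (`SSR_i/MSE_i = df1 * F_i`, each
#' asymptotically chi-square with `df1` degrees of freedom) and refers the
#' sum to the quadratic-Gaussian distribution implied by the cross-partition
#' correlation of the SSRs ([build_P()], [quadform_tail()]). With a single
#' partition this reduces exactly to [lr_test()].
#'
#' @param pg a `"partition_gls"` object.
#' @return a combined test-result.
#' @export
combined_lrt <- function(pg) {
  stopifnot(inherits(pg, "partition_gls"))
  stat <- sum(pg$df1 * pg$Fstat)
  Pm <- build_P(pg$cross$rho_ssr_mean, pg$n_p, pg$df1)
  combined_result(stat, quadform_tail(stat, Pm$eigenvalues), pg,
                  method = "Combined partition LRT",
                  df1 = pg$df1, df2 = NA_integer_)
}

#' Combined F-test across partitions (parametric bootstrap)
#'
#' The overall F-score is `(sum SSR_i / (n_p df1)) / (sum SSE_i / sum df2_i)`.
#' Its null distribution has no closed form: the numerator is drawn from the
#' quadratic-Gaussian distribution of the summed SSR (eigenvalue mixture of
#' chi-square(1)); the denominator from correlated Gaussians with mean 1 and
#' variance `2/df2_i` (correlation from the SSE cross-correlation), the
#' large-`df2` approximation of `SSE_i/df2_i`; the two are drawn
#' independently. The p-value is the fraction of bootstrap scores exceeding
#' the observed score.
#'
#' @param pg a `"partition_gls"` object.
#' @param n_boot number of bootstrap draws (>= 1e4; default 1e5).
#' @param seed RNG seed for the bootstrap.
#' @return a combined test-result with Monte-Carlo standard error `mc_se`.
#' @export
combined_f <- function(pg, n_boot = 1e5, seed = NULL) {
  stopifnot(inherits(pg, "partition_gls"))
  if (n_boot < 1e4) stop("n_boot must be at least 1e4")
  F_obs <- (sum(pg$SSR) / (pg$n_p * pg$df1)) / (sum(pg$SSE) / sum(pg$df2))
  draws <- with_seed(seed, boot_f_draws(pg, n_boot))
  p <- mean(draws$F >= F_obs)
  combined_result(F_obs, p, pg, method = "Combined partition F-test",
                  df1 = pg$df1, df2 = sum(pg$df2),
                  mc_se = sqrt(max(p * (1 - p), 1 / n_boot) / n_boot),
                  n_boot = n_boot, redraws = draws$redraws)
}

## bootstrap draws of the null F-score for a partition_gls configuration
boot_f_draws <- function(pg, n_boot) {
  n_p <- pg$n_p; df1 <- pg$df1
  lam <- build_P(pg$cross$rho_ssr_mean, n_p, df1)$eigenvalues
  num <- colSums(lam * matrix(stats::rchisq(n_boot * length(lam), 1),
                              length(lam), n_boot)) / (n_p * df1)
  ## denominator: correlated Gaussian approximation of SSE_i/df2_i
  sd_i <- sqrt(2 / pg$df2)
  Sig <- pg$cross$rho_sse_mean * tcrossprod(sd_i)
  diag(Sig) <- sd_i^2
  Ls <- chol(Sig)
  w <- pg$df2 / sum(pg$df2)
  redraws <- 0L
  den <- rep(NA_real_, n_boot)
  need <- seq_len(n_boot)
  while (length(need) > 0) {
    E <- 1 + matrix(stats::rnorm(length(need) * n_p), length(need)) %*% Ls
    bad <- rowSums(E <= 0) > 0
    den[need[!bad]] <- (E[!bad, , drop = FALSE] %*% w)
    redraws <- redraws + sum(bad)
    need <- need[bad]
  }
  if (redraws > 0)
    pg_log(sprintf("%d non-positive denominator draw(s) redrawn", redraws))
  list(F = num / den, redraws = redraws)
}

#' Combined t-test for one coefficient across partitions
#'
#' Tests the mean of the per-partition GLS estimates. The squared standard
#' error is `(1/n_p^2) sum_ij cor[b_i, b_j] se_i se_j`, with self-pairs at
#' correlation 1 and cross-pair correlations from the normalized
#' cross-partition coefficient covariance; the statistic is referred to a t
#' distribution with `sum_i df2_i` degrees of freedom. With one partition
#' this reduces exactly to [t_test()].
#'
#' @param pg a `"partition_gls"` object.
#' @param coef coefficient index or name.
#' @return a combined test-result (also carries `estimate` and `se`).
#' @export
combined_t <- function(pg, coef = 2L) {
  stopifnot(inherits(pg, "partition_gls"))
  if (is.character(coef)) coef <- match(coef, pg$labels)
  if (is.na(coef)) stop("unknown coefficient")
  b <- pg$coef[, coef]
  s <- pg$se[, coef]
  rho_b <- if (pg$n_p > 1) clip_rho(pg$cross$coef_cor_mean[coef]) else 0
  Rm <- matrix(rho_b, pg$n_p, pg$n_p)
  diag(Rm) <- 1
  se2 <- drop(crossprod(s, Rm %*% s)) / pg$n_p^2
  if (!is.finite(se2) || se2 <= 0) stop("non-finite combined standard error")
  stat <- mean(b) / sqrt(se2)
  df2 <- sum(pg$df2)
  combined_result(stat, 2 * stats::pt(abs(stat), df2, lower.tail = FALSE),
                  pg, method = "Combined partition t-test", df1 = 1L,
                  df2 = df2, estimate = mean(b), se = sqrt(se2),
                  coef_cor = rho_b)
}

#' Multiple-comparison baselines over per-partition p-values
#'
#' The comparison methods used by the validation harness: the minimum
#' Hochberg-adjusted p-value, the minimum Benjamini-Hochberg (FDR) adjusted
#' p-value, and the p-value of one randomly selected partition.
#'
#' @param p_values per-partition p-values.
#' @param alpha significance level for the reported decisions.
#' @param seed seed for the random-single-partition pick.
#' @return list with `hochberg`, `fdr`, `single` (p-values) and logical
#'   `reject_*` decisions at `alpha`.
#' @export
comparison_baselines <- function(p_values, alpha = 0.05, seed = NULL) {
  stopifnot(length(p_values) >= 1)
  ph <- min(stats::p.adjust(p_values, method = "hochberg"))
  pf_ <- min(stats::p.adjust(p_values, method = "BH"))
  ps <- p_values[with_seed(seed, sample.int(length(p_values), 1L))]
  list(hochberg = ph, fdr = pf_, single = ps,
       reject_hochberg = ph <= alpha, reject_fdr = pf_ <= alpha,
       reject_single = ps <= alpha)
}
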