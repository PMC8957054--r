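#' Spatial dataset container
#'
#' Bundles coordinates, a design matrix (first column the intercept) and a
#' response for N sites/pixels.
#'
#' @param coords N x 2 numeric matrix of site coordinates (map units).
#' @param X N x p design matrix; a column of ones is prepended if absent.
#' @param y numeric response vector, length N.
#' @param names optional predictor labels.
#' @param coord_tol duplicate-coordinate tolerance; duplicates trigger a
#'   warning (they are legal — the correlation of co-located points is
#'   `1 - nugget`).
#' @return object of class `"spatial_dataset"` with elements `coords`, `X`,
#'   `y`, `names`.
#' @export
spatial_dataset <- function(coords, X, y, names = NULL, coord_tol = 1e-8) {
  coords <- as.matrix(coords)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (ncol(coords) != 2L) stop("coords must have two columns")
  N <- nrow(coords)
  if (nrow(X) != N || length(y) != N) stop("coords, X and y disagree on N")
  if (!all(is.finite(coords)) || !all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in coords, X or y")
  if (ncol(X) == 0L || !all(abs(X[, 1] - 1) < 1e-12))
    X <- cbind(`(Intercept)` = 1, X)
  if (ncol(X) > N) stop("more predictors than observations")
  if (is.null(names)) names <- colnames(X) %||% paste0("b", seq_len(ncol(X)) - 1L)
  colnames(X) <- names
  dup <- duplicated(round(coords / max(coord_tol, 1e-300)))
  if (any(dup))
    warning(sprintf("%d duplicated coordinate rows (e.g. row %d)",
                    sum(dup), which(dup)[1]))
  structure(list(coords = coords, X = X, y = y, names = names),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("Spatial dataset: N = %d sites, p = %d predictors (%s)\n",
              nrow(x$X), ncol(x$X), paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Generalized least squares fit with a known correlation matrix
#'
#' Fits `y = X B + e` with `cor(e) = C` by whitening: with `D` such that
#' `D C D' = I`, the estimates are `B = (U'U)^{-1} U'Z` for `U = DX`,
#' `Z = Dy`. The error variance never needs separate estimation: every test
#' statistic downstream is a ratio invariant to it, so `C` (a correlation,
#' not a covariance) is used throughout.
#'
#' @param X design matrix (or a [spatial_dataset()], in which case `y` and
#'   `C` may be omitted and `C` built from `model`).
#' @param y response vector.
#' @param C correlation matrix, or `NULL` for independent errors.
#' @param D optional precomputed whitening matrix (from [whiten()]); pass it
#'   when fitting several models under the same `C`.
#' @param model optional [cor_model()] used to build `C` when `X` is a
#'   `spatial_dataset`.
#' @return object of class `"gls_fit"`: `coefficients`, `coef_cov`, `SSE`,
#'   `df2`, `MSE`, `logLik`, and whitened artifacts (`U`, `Z`, `qr`).
#' @export
gls_fit <- function(X, y = NULL, C = NULL, D = NULL, model = NULL) {
  if (inherits(X, "spatial_dataset")) {
    if (is.null(C) && is.null(D) && !is.null(model))
      C <- build_correlation(X$coords, model)
    y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X); p <- ncol(X)
  if (p >= 1 && N <= p) stop("need N > p observations")
  if (is.null(D)) {
    if (is.null(C)) {
      D <- diag(N)
      attr(D, "logdet") <- 0
    } else D <- whiten(C)
  }
  U <- D %*% X
  Z <- drop(D %*% y)
  fit_whitened(U, Z, logdetC = attr(D, "logdet") %||% NA_real_,
               D = D, labels = colnames(X))
}

## Core fit on whitened data; shared by gls_fit and the partition driver.
fit_whitened <- function(U, Z, logdetC = NA_real_, D = NULL, labels = NULL) {
  N <- length(Z)
  p <- ncol(U)
  if (p == 0L) {                      # empty model: mean fixed at zero
    SSE <- sum(Z^2)
    out <- list(coefficients = numeric(0), coef_cov = matrix(0, 0, 0),
                SSE = SSE, df2 = N, MSE = SSE / N, N = N, p = 0L,
                U = U, Z = Z, qr = NULL, D = D, logdetC = logdetC)
    class(out) <- "gls_fit"
    return(out)
  }
  qrU <- qr(U)
  if (qrU$rank < p) {
    bad <- colnames(U)[qrU$pivot[(qrU$rank + 1L):p]] %||% "(unnamed)"
    stop("design is rank-deficient after whitening; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coef <- drop(qr.coef(qrU, Z))
  resid <- drop(qr.resid(qrU, Z))     # (I - H) Z
  SSE <- sum(resid^2)
  df2 <- N - p
  MSE <- SSE / df2
  XtX_inv <- chol2inv(chol(crossprod(U)))   # (U'U)^{-1}; p is small
  coef_cov <- MSE * XtX_inv
  if (!is.null(labels)) {
    names(coef) <- labels
    dimnames(coef_cov) <- list(labels, labels)
  }
  s2ml <- SSE / N
  ll <- if (is.finite(logdetC))
    -0.5 * (N * log(2 * pi * s2ml) + logdetC + N) else NA_real_
  out <- list(coefficients = coef, coef_cov = coef_cov, SSE = SSE,
              df2 = df2, MSE = MSE, N = N, p = p, logLik = ll,
              U = U, Z = Z, qr = qrU, D = D, logdetC = logdetC)
  class(out) <- "gls_fit"
  out
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("GLS fit: N = %d, p = %d, SSE = %.6g, df2 = %d, MSE = %.6g\n",
              x$N, x$p, x$SSE, x$df2, x$MSE))
  if (x$p > 0) {
    se <- sqrt(diag(x$coef_cov))
    print(cbind(Estimate = x$coefficients, `Std.Error` = se))
  }
  invisible(x)
}

## thin-Q of the whitened design (columns: orthonormal basis of span(U))
gls_Q <- function(fit) {
  if (fit$p == 0L) matrix(0, fit$N, 0L) else qr.Q(fit$qr)
}

test_result <- function(statistic, df1, df2, p_value, method, ...) {
  structure(list(statistic = statistic, df1 = df1, df2 = df2,
                 p_value = min(max(p_value, 0), 1), method = method, ...),
            class = "pg_test")
}

#' @export
print.pg_test <- function(x, ...) {
  dfs <- if (is.null(x$df2) || is.na(x$df2)) sprintf("df = %g", x$df1)
         else sprintf("df1 = %g, df2 = %g", x$df1, x$df2)
  cat(sprintf("%s: statistic = %.5g, %s, p = %.4g\n",
              x$method, x$statistic, dfs, x$p_value))
  if (!is.null(x$mc_se)) cat(sprintf("  (Monte-Carlo se of p: %.2g)\n", x$mc_se))
  invisible(x)
}

check_nested <- function(full, reduced) {
  if (!inherits(full, "gls_fit") || !inherits(reduced, "gls_fit"))
    stop("full and reduced must be gls_fit objects")
  if (full$N != reduced$N) stop("full and reduced fit different datasets")
  if (reduced$p >= full$p)
    stop("models are not nested: reduced model must have fewer predictors")
  ## reduced design must lie in the span of the full design
  if (reduced$p > 0) {
    Q <- gls_Q(full)
    resid <- reduced$U - Q %*% crossprod(Q, reduced$U)
    if (max(abs(resid)) > 1e-6 * max(1, max(abs(reduced$U))))
      stop("models are not nested: reduced design is not in the span of the full design")
  }
  invisible(TRUE)
}

#' GLS F-test of a full against a nested reduced model
#'
#' `F = (SSR_{1-0}/df1) / (SSE/df2)` with `SSR_{1-0} = SSE_0 - SSE`, compared
#' to the F(df1, df2) upper tail. Both fits must use the same correlation
#' matrix.
#'
#' @param full,reduced [gls_fit()] objects for the full and reduced models.
#' @return a test-result object (`statistic`, `df1`, `df2`, `p_value`).
#' @export
f_test <- function(full, reduced) {
  check_nested(full, reduced)
  df1 <- full$p - reduced$p
  SSR <- max(reduced$SSE - full$SSE, 0)
  stat <- (SSR / df1) / full$MSE
  test_result(stat, df1, full$df2,
              stats::pf(stat, df1, full$df2, lower.tail = FALSE),
              method = "GLS F-test", SSR = SSR)
}

#' GLS likelihood-ratio test of a full against a nested reduced model
#'
#' On the deviance scale the log-likelihood-ratio statistic is
#' `SSR_{1-0}` scaled to unit error variance, i.e. `SSR_{1-0}/MSE = df1 * F`,
#' compared to the chi-square(df1) upper tail. For large `df2` this agrees
#' with [f_test()].
#'
#' @inheritParams f_test
#' @return a test-result object.
#' @export
lr_test <- function(full, reduced) {
  check_nested(full, reduced)
  df1 <- full$p - reduced$p
  SSR <- max(reduced$SSE - full$SSE, 0)
  stat <- SSR / full$MSE
  test_result(stat, df1, NA_integer_,
              stats::pchisq(stat, df1, lower.tail = FALSE),
              method = "GLS LRT", SSR = SSR)
}

#' GLS t-test for a single coefficient
#'
#' @param fit a [gls_fit()].
#' @param coef coefficient index or name.
#' @return a test-result object; `statistic` is `estimate / se`, two-sided
#'   p-value from t(df2).
#' @export
t_test <- function(fit, coef = 2L) {
  if (is.character(coef)) coef <- match(coef, names(fit$coefficients))
  if (is.na(coef) || coef < 1 || coef > fit$p) stop("unknown coefficient")
  se <- sqrt(diag(fit$coef_cov))[coef]
  if (!is.finite(se) || se == 0) stop("zero or non-finite standard error")
  stat <- unname(fit$coefficients[coef] / se)
  test_result(stat, 1L, fit$df2,
              2 * stats::pt(abs(stat), fit$df2, lower.tail = FALSE),
              method = "GLS t-test", estimate = unname(fit$coefficients[coef]),
              se = unname(se))
}

#' Reduced design matrix for a nested hypothesis
#'
#' Either drop named/indexed columns, or impose a linear restriction
#' `L B = 0` (for orthogonal contrasts), in which case the reduced design is
#' `X N` with `N` a basis of the null space of `L`.
#'
#' @param X full design matrix.
#' @param drop column names or indices to remove.
#' @param restrict q x p restriction matrix `L`.
#' @return the reduced design matrix (possibly with zero columns).
#' @export
reduced_design <- function(X, drop = NULL, restrict = NULL) {
  X <- as.matrix(X)
  if (!is.null(drop)) {
    if (is.character(drop)) drop <- match(drop, colnames(X))
    if (anyNA(drop)) stop("unknown column in drop=")
    return(X[, -drop, drop = FALSE])
  }
  if (!is.null(restrict)) {
    L <- as.matrix(restrict)
    if (ncol(L) != ncol(X)) stop("restriction matrix has wrong width")
    ns <- qr(t(L))
    Nb <- qr.Q(ns, complete = TRUE)[, -seq_len(ns$rank), drop = FALSE]
    return(X %*% Nb)
  }
  stop("supply drop= or restrict=")
}
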