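#' Random partition scheme
#'
#' Splits `N` rows into `n_p` disjoint equal-size random subsets of size
#' `floor(N/n_p)`; the remainder rows (fewer than `n_p`) are dropped and
#' reported, unless `redistribute = TRUE`, in which case they are spread one
#' each over the first partitions (producing unequal sizes, which all
#' downstream formulas support).
#'
#' @param N number of rows.
#' @param n_p number of partitions.
#' @param seed RNG seed (scheme is deterministic given the seed).
#' @param redistribute keep remainder rows by unequal partition sizes.
#' @return object of class `"partition_scheme"`: `n_p`, `sizes`,
#'   `assignment` (length-N integer labels, `NA` = dropped), `seed`.
#' @export
make_partitions <- function(N, n_p, seed = NULL, redistribute = FALSE) {
  stopifnot(n_p >= 1, N >= n_p)
  perm <- with_seed(seed, sample.int(N))
  m <- N %/% n_p
  rem <- N - m * n_p
  sizes <- rep(m, n_p)
  if (redistribute && rem > 0) sizes[seq_len(rem)] <- m + 1L
  assignment <- rep(NA_integer_, N)
  assignment[perm[seq_len(sum(sizes))]] <- rep.int(seq_len(n_p), sizes)
  if (!redistribute && rem > 0)
    pg_log(sprintf("%d remainder row(s) dropped from the partitioning", rem))
  structure(list(n_p = n_p, sizes = sizes, assignment = assignment,
                 seed = seed, dropped = which(is.na(assignment))),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("Partition scheme: n_p = %d, sizes = %s, %d dropped\n",
              x$n_p, paste(unique(x$sizes), collapse = "/"),
              length(x$dropped)))
  invisible(x)
}

#' Export / import partition assignments
#'
#' Two-column table (`row`, `partition`) for reproducibility; dropped rows
#' have an empty partition label.
#' @param scheme a [make_partitions()] scheme.
#' @param path file path.
#' @name partition_io
#' @export
write_partitions <- function(scheme, path) {
  utils::write.csv(data.frame(row = seq_along(scheme$assignment),
                              partition = scheme$assignment),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname partition_io
#' @export
read_partitions <- function(path) {
  df <- utils::read.csv(path)
  assignment <- as.integer(df$partition[order(df$row)])
  n_p <- max(assignment, na.rm = TRUE)
  structure(list(n_p = n_p, sizes = tabulate(assignment, n_p),
                 assignment = assignment, seed = NULL,
                 dropped = which(is.na(assignment))),
            class = "partition_scheme")
}

#' Whitened cross-partition correlation block
#'
#' `R_ij = D_i C_ij D_j'`: the correlation matrix of the *whitened* errors
#' of two partitions, from the raw cross-correlation block `C_ij` and the
#' partitions' whitening matrices.
#'
#' @param D_i,D_j whitening matrices of the two partitions.
#' @param C_ij cross-correlation block (rows of partition i x rows of j).
#' @return `m_i` x `m_j` matrix.
#' @export
cross_whitened_correlation <- function(D_i, D_j, C_ij) {
  if (ncol(D_i) != nrow(C_ij) || ncol(D_j) != ncol(C_ij))
    stop("dimension mismatch between whitening matrices and C_ij")
  D_i %*% C_ij %*% t(D_j)
}

## sum(M^2) for M = t(A) %*% R %*% B, the trace-identity building block:
## vec(AA')'(R (x) R) vec(BB') = tr(AA' R BB' R') = ||A' R B||_F^2
tr_block <- function(A, R, B) {
  M <- crossprod(A, R %*% B)
  sum(M * M)
}

#' Correlation between the SSR statistics of two partitions
#'
#' Evaluates `vec(H_i - H0_i)' (R_ij x R_ij) vec(H_j - H0_j) / df1` without
#' materializing the Kronecker product, via the trace identity
#' `tr((H_i - H0_i) R_ij (H_j - H0_j) R_ij')`. The hat matrices enter
#' through thin orthonormal bases `Q` (full model) and `Q0` (reduced).
#'
#' @param Q_i,Q0_i,Q_j,Q0_j thin-Q factors of the whitened designs.
#' @param R_ij whitened cross-correlation from
#'   [cross_whitened_correlation()].
#' @return scalar correlation (1 for the self pair).
#' @export
rho_ssr <- function(Q_i, Q0_i, Q_j, Q0_j, R_ij) {
  df1 <- ncol(Q_i) - ncol(Q0_i)
  if (df1 != ncol(Q_j) - ncol(Q0_j)) stop("partitions disagree on df1")
  (tr_block(Q_i, R_ij, Q_j) - tr_block(Q_i, R_ij, Q0_j) -
     tr_block(Q0_i, R_ij, Q_j) + tr_block(Q0_i, R_ij, Q0_j)) / df1
}

#' Correlation between the SSE statistics of two partitions
#'
#' Evaluates `vec(I - H_i)' (R_ij x R_ij) vec(I - H_j) / sqrt(df2_i df2_j)`
#' through the same Kronecker-free trace identity.
#'
#' @inheritParams rho_ssr
#' @return scalar (1 for the self pair).
#' @export
rho_sse <- function(Q_i, Q_j, R_ij) {
  df2_i <- nrow(Q_i) - ncol(Q_i)
  df2_j <- nrow(Q_j) - ncol(Q_j)
  tRQj <- R_ij %*% Q_j
  QitR <- crossprod(Q_i, R_ij)
  (sum(R_ij^2) - sum(QitR^2) - sum(tRQj^2) + tr_block(Q_i, R_ij, Q_j)) /
    sqrt(df2_i * df2_j)
}

#' Cross-partition covariance of the coefficient estimates
#'
#' The unit-variance cross covariance
#' `(U_i'U_i)^{-1} (U_i' R_ij U_j) (U_j'U_j)^{-1}` between the GLS
#' coefficient estimators of two partitions. For the self pair (`R_ii = I`)
#' this is `(U_i'U_i)^{-1}`; correlations are obtained by normalizing by the
#' self-pair diagonals (see [partition_gls()]).
#'
#' @param fit_i,fit_j per-partition full-model [gls_fit()] objects.
#' @param R_ij whitened cross-correlation block.
#' @return p x p matrix.
#' @export
coef_cross_covariance <- function(fit_i, fit_j, R_ij) {
  ## (U'U)^{-1}U' = R^{-1}Q' from the QR factorization
  Ri <- qr.R(fit_i$qr); Qi <- gls_Q(fit_i)
  Rj <- qr.R(fit_j$qr); Qj <- gls_Q(fit_j)
  pi_ <- order(fit_i$qr$pivot); pj_ <- order(fit_j$qr$pivot)
  M <- crossprod(Qi, R_ij %*% Qj)
  V <- backsolve(Ri, t(backsolve(Rj, t(M))))
  V[pi_, pj_, drop = FALSE]
}

## ---- partition design: everything that depends only on geometry + X ----

#' Precompute the partition design for repeated analyses under one geometry
#'
#' Builds, once, everything that does not depend on the response: the
#' per-partition whitening matrices, whitened designs and hat-matrix
#' factors, and the cross-partition correlations (`rho_SSR`, `rho_SSE`,
#' coefficient correlations) averaged over a random subset of partition
#' pairs. Use [pgls_apply()] to analyze one or many responses under the
#' cached design; [partition_gls()] wraps both for the one-shot case.
#'
#' @param coords,X site coordinates and full design matrix.
#' @param model a [cor_model()] with all parameters fixed.
#' @param scheme a [make_partitions()] scheme (or `n_p` to build one).
#' @param reduced specification of the reduced model: list with `drop`
#'   (columns) or `restrict` (matrix); default drops all non-intercept
#'   columns.
#' @param n_p number of partitions when `scheme` is not given.
#' @param pair_budget maximum number of partition pairs on which the
#'   cross-partition correlations are evaluated (default
#'   `min(15, n_p(n_p-1)/2)`, mirroring the validation studies); the mean is
#'   used for all pairs downstream, and the per-pair spread is reported.
#' @param seed RNG seed for the partition scheme and the pair subsample.
#' @return object of class `"pgls_design"`.
#' @export
pgls_design <- function(coords, X, model, scheme = NULL, reduced = NULL,
                        n_p = 8, pair_budget = NULL, seed = NULL) {
  coords <- as.matrix(coords); X <- as.matrix(X)
  N <- nrow(X)
  p <- ncol(X)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2L))
  if (is.null(scheme)) scheme <- make_partitions(N, n_p, seed = seeds[1])
  n_p <- scheme$n_p
  if (min(scheme$sizes) < p + 2L)
    stop("partitions too small for the model: need at least p + 2 rows each")
  X0 <- reduced_model_matrix(X, reduced)
  df1 <- p - ncol(X0)
  parts <- lapply(seq_len(n_p), function(i) {
    idx <- which(scheme$assignment == i)
    C_i <- build_correlation(coords[idx, , drop = FALSE], model)
    D_i <- whiten(C_i)
    fit_frame(D_i, X[idx, , drop = FALSE], X0[idx, , drop = FALSE],
              idx = idx, nugget = model$nugget)
  })
  pairs <- choose_pairs(n_p, pair_budget, seed = seeds[2])
  cross <- cross_partition_stats(parts, coords, model, pairs)
  structure(list(scheme = scheme, parts = parts, model = model, X0cols = ncol(X0),
                 df1 = df1, p = p, labels = colnames(X), cross = cross,
                 coords = coords, seed = seed),
            class = "pgls_design")
}

reduced_model_matrix <- function(X, reduced) {
  if (is.null(reduced)) {
    keep <- which(apply(X, 2, function(v) all(abs(v - v[1]) < 1e-12)))[1]
    if (is.na(keep)) stop("no intercept column found; give reduced= explicitly")
    return(X[, keep, drop = FALSE])
  }
  if (is.matrix(reduced)) return(reduced_design(X, restrict = reduced))
  if (is.list(reduced)) return(reduced_design(X, drop = reduced$drop,
                                              restrict = reduced$restrict))
  reduced_design(X, drop = reduced)
}

## per-partition frame: whitening + whitened full/reduced designs
fit_frame <- function(D_i, X_i, X0_i, idx, nugget) {
  U <- D_i %*% X_i
  U0 <- if (ncol(X0_i) > 0) D_i %*% X0_i else matrix(0, nrow(U), 0L)
  qrU <- qr(U)
  Q <- qr.Q(qrU)
  Q0 <- if (ncol(U0) > 0) qr.Q(qr(U0)) else matrix(0, nrow(U), 0L)
  list(idx = idx, D = D_i, U = U, qr = qrU, Q = Q, Q0 = Q0,
       m = length(idx), df2 = length(idx) - ncol(U),
       UtU_inv = chol2inv(chol(crossprod(U))), nugget = nugget,
       logdetC = attr(D_i, "logdet"))
}

choose_pairs <- function(n_p, pair_budget, seed = NULL) {
  if (n_p == 1L) return(matrix(integer(0), 0, 2))
  all_pairs <- t(utils::combn(n_p, 2L))
  budget <- pair_budget %||% min(15L, nrow(all_pairs))
  if (budget < 1) stop("pair_budget must be at least 1 when n_p > 1")
  budget <- min(budget, nrow(all_pairs))
  sel <- with_seed(seed, sample.int(nrow(all_pairs), budget))
  all_pairs[sel, , drop = FALSE]
}

cross_partition_stats <- function(parts, coords, model, pairs) {
  p <- ncol(parts[[1]]$U)
  if (nrow(pairs) == 0L)
    return(list(pairs = pairs, rho_ssr = numeric(0), rho_sse = numeric(0),
                coef_cor = matrix(numeric(0), 0, p),
                rho_ssr_mean = 0, rho_sse_mean = 0,
                coef_cor_mean = rep(0, p)))
  rs <- re <- numeric(nrow(pairs))
  cc <- matrix(NA_real_, nrow(pairs), p)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    pi_ <- parts[[i]]; pj_ <- parts[[j]]
    C_ij <- cross_correlation(coords[pi_$idx, , drop = FALSE],
                              coords[pj_$idx, , drop = FALSE],
                              modify_nugget(model, pi_$nugget),
                              nugget_j = pj_$nugget)
    R_ij <- cross_whitened_correlation(pi_$D, pj_$D, C_ij)
    rs[k] <- rho_ssr(pi_$Q, pi_$Q0, pj_$Q, pj_$Q0, R_ij)
    re[k] <- rho_sse(pi_$Q, pj_$Q, R_ij)
    M <- crossprod(pi_$Q, R_ij %*% pj_$Q)
    Vij <- backsolve(qr.R(pi_$qr), t(backsolve(qr.R(pj_$qr), t(M))))
    Vij <- Vij[order(pi_$qr$pivot), order(pj_$qr$pivot), drop = FALSE]
    cc[k, ] <- diag(Vij) / sqrt(diag(pi_$UtU_inv) * diag(pj_$UtU_inv))
  }
  list(pairs = pairs, rho_ssr = rs, rho_sse = re, coef_cor = cc,
       rho_ssr_mean = clip_rho(mean(rs)), rho_sse_mean = clip_rho(mean(re)),
       coef_cor_mean = colMeans(cc))
}

modify_nugget <- function(model, nugget) {
  if (is.null(nugget) || nugget == model$nugget) return(model)
  m <- model; m$nugget <- nugget; m
}

clip_rho <- function(rho) {
  if (any(rho < 0)) {
    pg_log(sprintf("clipping %d negative rho estimate(s) to 0",
                   sum(rho < 0)))
    rho[rho < 0] <- 0
  }
  if (any(rho > 1)) rho[rho > 1] <- 1
  rho
}

#' Analyze one response vector under a cached partition design
#'
#' @param design a [pgls_design()].
#' @param y response vector for the full dataset (the design's scheme picks
#'   the rows).
#' @return object of class `"partition_gls"` holding per-partition
#'   statistics (`SSR`, `SSE`, `df2`, `MSE`, F and p per partition),
#'   coefficient estimates and standard errors, and the cross-partition
#'   correlation summaries; feed it to [combined_lrt()], [combined_f()],
#'   [combined_t()].
#' @export
pgls_apply <- function(design, y) {
  y <- as.numeric(y)
  n_p <- design$scheme$n_p
  df1 <- design$df1
  p <- design$p
  SSR <- SSE <- df2 <- numeric(n_p)
  coef <- se <- matrix(NA_real_, n_p, p, dimnames = list(NULL, design$labels))
  for (i in seq_len(n_p)) {
    fr <- design$parts[[i]]
    Z <- drop(fr$D %*% y[fr$idx])
    cf <- crossprod(fr$Q, Z)          # coordinates in the full-model basis
    c0 <- crossprod(fr$Q0, Z)
    SSE[i] <- sum(Z^2) - sum(cf^2)
    SSR[i] <- max(sum(cf^2) - sum(c0^2), 0)
    df2[i] <- fr$df2
    coef[i, ] <- qr.coef(fr$qr, Z)
    se[i, ] <- sqrt((SSE[i] / fr$df2) * diag(fr$UtU_inv))
  }
  MSE <- SSE / df2
  Fstat <- (SSR / df1) / MSE
  structure(list(
    n_p = n_p, df1 = df1, SSR = SSR, SSE = SSE, df2 = df2, MSE = MSE,
    Fstat = Fstat,
    p_f = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
    coef = coef, se = se, cross = design$cross,
    scheme = design$scheme, model = design$model, labels = design$labels
  ), class = "partition_gls")
}

#' Partitioned GLS analysis
#'
#' One-shot driver: partitions the dataset, fits full and reduced GLS models
#' in every partition, computes the cross-partition correlations of the test
#' statistics on a random subset of partition pairs, and returns the
#' per-partition results ready for combination. With
#' `estimate_nugget = TRUE`, the nugget of the correlation model is
#' estimated separately in each partition by maximum likelihood (the
#' combined tests are then conditional on those estimates).
#'
#' @param data a [spatial_dataset()].
#' @param model a [cor_model()]; its nugget is the starting/fixed value.
#' @param reduced reduced-model specification (see [pgls_design()]).
#' @param n_p number of partitions.
#' @param pair_budget number of partition pairs to evaluate.
#' @param seed RNG seed (partition scheme + pair subsample).
#' @param estimate_nugget estimate the nugget per partition by ML.
#' @param scheme optional pre-built [make_partitions()] scheme.
#' @return a `"partition_gls"` object (see [pgls_apply()]).
#' @export
partition_gls <- function(data, model, reduced = NULL, n_p = 8,
                          pair_budget = NULL, seed = NULL,
                          estimate_nugget = FALSE, scheme = NULL) {
  stopifnot(inherits(data, "spatial_dataset"))
  if (!estimate_nugget) {
    des <- pgls_design(data$coords, data$X, model, scheme = scheme,
                       reduced = reduced, n_p = n_p,
                       pair_budget = pair_budget, seed = seed)
    return(pgls_apply(des, data$y))
  }
  ## nugget estimated per partition: whitening depends on y, no caching
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2L))
  if (is.null(scheme))
    scheme <- make_partitions(nrow(data$X), n_p, seed = seeds[1])
  n_p <- scheme$n_p
  X0 <- reduced_model_matrix(data$X, reduced)
  p <- ncol(data$X)
  df1 <- p - ncol(X0)
  parts <- vector("list", n_p)
  SSR <- SSE <- df2 <- nug <- numeric(n_p)
  coef <- se <- matrix(NA_real_, n_p, p, dimnames = list(NULL, colnames(data$X)))
  for (i in seq_len(n_p)) {
    idx <- which(scheme$assignment == i)
    est <- estimate_nugget_ml(data$y[idx], data$X[idx, , drop = FALSE],
                              data$coords[idx, , drop = FALSE], model)
    nug[i] <- est$nugget
    D_i <- est$D
    fr <- fit_frame(D_i, data$X[idx, , drop = FALSE],
                    X0[idx, , drop = FALSE], idx = idx, nugget = est$nugget)
    parts[[i]] <- fr
    Z <- drop(D_i %*% data$y[idx])
    cf <- crossprod(fr$Q, Z); c0 <- crossprod(fr$Q0, Z)
    SSE[i] <- sum(Z^2) - sum(cf^2)
    SSR[i] <- max(sum(cf^2) - sum(c0^2), 0)
    df2[i] <- fr$df2
    coef[i, ] <- qr.coef(fr$qr, Z)
    se[i, ] <- sqrt((SSE[i] / fr$df2) * diag(fr$UtU_inv))
  }
  pairs <- choose_pairs(n_p, pair_budget, seed = seeds[2])
  cross <- cross_partition_stats(parts, data$coords, model, pairs)
  MSE <- SSE / df2
  Fstat <- (SSR / df1) / MSE
  structure(list(
    n_p = n_p, df1 = df1, SSR = SSR, SSE = SSE, df2 = df2, MSE = MSE,
    Fstat = Fstat, p_f = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
    coef = coef, se = se, cross = cross, scheme = scheme, model = model,
    nuggets = nug, labels = colnames(data$X)
  ), class = "partition_gls")
}

#' @export
print.partition_gls <- function(x, ...) {
  cat(sprintf("Partitioned GLS: n_p = %d, df1 = %d, total df2 = %d\n",
              x$n_p, x$df1, sum(x$df2)))
  cat(sprintf("  mean rho_SSR = %.4f, mean rho_SSE = %.4f\n",
              x$cross$rho_ssr_mean, x$cross$rho_sse_mean))
  tab <- data.frame(SSR = x$SSR, SSE = x$SSE, df2 = x$df2, F = x$Fstat,
                    p = x$p_f)
  print(tab, digits = 4)
  invisible(x)
}
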