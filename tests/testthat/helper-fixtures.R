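## shared fixture builders; everything is generated in code under fixed seeds

random_spd <- function(m, seed = 1) {
  with_seed(seed, {
    A <- matrix(rnorm(m * m), m)
    S <- crossprod(A) + m * diag(m)
    d <- sqrt(diag(S))
    S / tcrossprod(d)          # correlation-like SPD matrix
  })
}

## small spatial dataset with known exponential correlation
small_spatial <- function(N = 40, range = 0.3, b = 0, sigma = 1, seed = 1,
                          p_extra = 1) {
  with_seed(seed, {
    coords <- matrix(runif(2 * N), N, 2)
    model <- cor_model("exponential", range = range)
    C <- build_correlation(coords, model)
    X <- cbind(1, matrix(rnorm(N * p_extra), N))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p_extra)))
    y <- drop(X %*% c(0, rep(b, p_extra))) +
      sigma * drop(crossprod(chol(C), rnorm(N)))
    list(data = spatial_dataset(coords, X, y), model = model, C = C)
  })
}

expect_within <- function(value, target, tol) {
  expect_lt(abs(value - target), tol)
}
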