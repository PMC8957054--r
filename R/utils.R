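#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so seeded helpers do not perturb an enclosing simulation stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

## condition helper: package messages are signalled, never cat()ed, so callers
## can suppressMessages() simulation loops.
pg_log <- function(...) message("partGLS: ", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise Euclidean distances between two coordinate sets
#'
#' @param a,b numeric matrices with 2 columns (map units). If `b` is missing,
#'   distances within `a` are returned.
#' @return an `nrow(a)` x `nrow(b)` matrix of distances.
#' @export
cross_dist <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
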