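#' Spatial correlation model
#'
#' Describes how the correlation between the errors at two locations decays
#' with the distance `d` between them:
#' \deqn{v(d) = (1 - nugget)\,\exp(-(d/r)^g), \qquad v(0) = 1,}
#' with range `r` (map units), shape `g` (`g = 1` is the exponential family)
#' and a nugget in `[0, 1)` giving the fraction of error variance that is
#' local (spatially uncorrelated).
#'
#' @param family `"exponential"` (shape fixed at 1) or `"exponential_power"`.
#' @param range positive range parameter `r`, in the units of the coordinates.
#' @param shape positive shape parameter `g`; forced to 1 for the exponential
#'   family.
#' @param nugget nugget proportion in `[0, 1)`.
#' @return an object of class `"cor_model"`.
#' @examples
#' m <- cor_model("exponential", range = 0.1)
#' cor_at(m, c(0, 0.1, 0.5))
#' @export
cor_model <- function(family = c("exponential", "exponential_power"),
                      range, shape = 1, nugget = 0) {
  family <- match.arg(family)
  if (family == "exponential") shape <- 1
  stopifnot(is.numeric(range), length(range) == 1L, is.finite(range), range > 0,
            is.numeric(shape), length(shape) == 1L, is.finite(shape), shape > 0,
            is.numeric(nugget), length(nugget) == 1L, nugget >= 0, nugget < 1)
  structure(list(family = family, range = range, shape = shape, nugget = nugget),
            class = "cor_model")
}

#' @export
print.cor_model <- function(x, ...) {
  cat(sprintf("Correlation model: %s, range = %g, shape = %g, nugget = %g\n",
              x$family, x$range, x$shape, x$nugget))
  invisible(x)
}

#' Evaluate a correlation model at given distances
#'
#' @param model a [cor_model()].
#' @param d numeric vector/matrix of distances; `d = 0` maps to exactly 1.
#' @param zero_is_one should `d == 0` return 1 (same location, within-set) or
#'   `1 - nugget` (distinct co-located points)? The diagonal of a correlation
#'   matrix uses `TRUE`; cross-set blocks use `FALSE`.
#' @return correlations, same shape as `d`.
#' @export
cor_at <- function(model, d, zero_is_one = TRUE) {
  v <- (1 - model$nugget) * exp(-(d / model$range)^model$shape)
  if (zero_is_one) v[d == 0] <- 1
  v
}

#' Build the correlation matrix for a set of locations
#'
#' @param coords N x 2 matrix of coordinates.
#' @param model a [cor_model()].
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
build_correlation <- function(coords, model) {
  d <- cross_dist(coords)
  C <- cor_at(model, d, zero_is_one = FALSE)
  diag(C) <- 1
  (C + t(C)) / 2
}

#' Cross-correlation block between two sets of locations
#'
#' Entries are `v(d)` for the distances between every location of the first
#' set and every location of the second; co-located *distinct* points get
#' `1 - nugget`, not 1. When the two sets carry different nugget estimates,
#' supply `nugget_j` and the attenuation is the geometric mean
#' `sqrt((1-nug_i)(1-nug_j))`.
#'
#' @param coords_i,coords_j coordinate matrices.
#' @param model a [cor_model()] (its nugget is the first set's).
#' @param nugget_j optional nugget for the second set.
#' @return `nrow(coords_i)` x `nrow(coords_j)` matrix.
#' @export
cross_correlation <- function(coords_i, coords_j, model, nugget_j = NULL) {
  d <- cross_dist(coords_i, coords_j)
  v <- exp(-(d / model$range)^model$shape)
  att <- if (is.null(nugget_j)) 1 - model$nugget else
    sqrt((1 - model$nugget) * (1 - nugget_j))
  att * v
}

## Cholesky with a jitter ladder: adds 1e-10, 1e-8, 1e-6 to the diagonal
## before failing; each escalation is signalled as a message.
chol_jitter <- function(C, jitters = c(0, 1e-10, 1e-8, 1e-6)) {
  for (j in jitters) {
    Cj <- C
    if (j > 0) {
      diag(Cj) <- diag(Cj) + j
      pg_log(sprintf("adding jitter %g to the correlation diagonal", j))
    }
    R <- tryCatch(chol(Cj), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  stop(sprintf(paste0("correlation matrix is not positive definite even after ",
                      "jitter (smallest eigenvalue %.3e); the correlation model ",
                      "is ill-conditioned for these locations"), ev))
}

#' Whitening matrix of a correlation matrix
#'
#' Returns the lower-triangular matrix `D` with `D C D' = I`: the inverse of
#' the lower Cholesky factor of `C`. Transforming data by `D` makes the
#' errors uncorrelated with unit variance.
#'
#' @param C symmetric positive-definite matrix.
#' @return lower-triangular matrix `D` with attribute `"logdet"` holding
#'   `log det(C)`.
#' @export
whiten <- function(C) {
  R <- chol_jitter(C)                      # C = R'R, upper R
  D <- forwardsolve(t(R), diag(nrow(C)))   # inv of lower factor
  attr(D, "logdet") <- 2 * sum(log(diag(R)))
  D
}
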