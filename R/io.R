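#' Read a pixel/site table from delimited text
#'
#' Expects a header with coordinate columns `x` and `y`, one response
#' column and any number of predictor columns. Missing or non-numeric
#' cells are rejected with a row/column report.
#'
#' @param path file path (comma-delimited by default).
#' @param response response column name.
#' @param predictors predictor column names (default: everything that is
#'   not a coordinate or the response).
#' @param sep field delimiter (`","` or `"\t"`).
#' @return a [spatial_dataset()].
#' @export
read_pixel_table <- function(path, response = "y_obs", predictors = NULL,
                             sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  need <- c("x", "y", response)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(predictors)) predictors <- setdiff(names(df), need)
  for (cl in c(need, predictors)) {
    v <- df[[cl]]
    if (!is.numeric(v))
      stop(sprintf("column '%s' is not numeric", cl))
    if (anyNA(v))
      stop(sprintf("missing values in column '%s' at row(s): %s", cl,
                   paste(utils::head(which(is.na(v)), 10), collapse = ", ")))
  }
  X <- as.matrix(df[predictors])
  if (length(predictors) == 0L) X <- matrix(numeric(0), nrow(df), 0)
  message(sprintf("read %d rows, %d predictor(s) from %s", nrow(df),
                  length(predictors), path))
  spatial_dataset(cbind(df$x, df$y), X, df[[response]])
}

#' Write a spatial dataset as delimited text
#'
#' @param data a [spatial_dataset()].
#' @param path output path.
#' @param response response column name.
#' @param sep delimiter.
#' @return `path`, invisibly.
#' @export
write_pixel_table <- function(data, path, response = "y_obs", sep = ",") {
  pred <- data$X[, -1, drop = FALSE]
  if (any(colnames(pred) %in% c("x", "y", response)))
    stop("predictor names clash with the coordinate/response columns")
  df <- data.frame(x = data$coords[, 1], y = data$coords[, 2],
                   check.names = FALSE)
  df[[response]] <- data$y
  for (j in seq_len(ncol(pred))) df[[colnames(pred)[j]]] <- pred[, j]
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a pixel-by-time matrix from delimited text
#'
#' First columns `x`, `y`; remaining columns are time points in order (the
#' header carries the time labels).
#'
#' @param path file path.
#' @param sep delimiter.
#' @return list: `coords`, `zmat` (N x T), `times` (parsed from the header
#'   when numeric, else `1:T`).
#' @export
read_pixel_time_matrix <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("missing coordinate column(s) x/y")
  tc <- setdiff(names(df), c("x", "y"))
  if (length(tc) < 3) stop("need at least 3 time columns")
  zmat <- as.matrix(df[tc])
  if (anyNA(zmat) || !is.numeric(zmat))
    stop("non-numeric or missing values in the time columns")
  coords <- cbind(df$x, df$y)
  if (anyNA(coords)) stop("missing coordinates")
  dup <- which(duplicated(round(coords * 1e8)))
  if (length(dup))
    warning("duplicated coordinates at row(s): ",
            paste(utils::head(dup, 10), collapse = ", "))
  times <- suppressWarnings(as.numeric(tc))
  if (anyNA(times)) times <- seq_along(tc)
  list(coords = coords, zmat = zmat, times = times)
}

#' Write a pixel-by-time matrix as delimited text
#'
#' @param zmat N x T matrix.
#' @param coords N x 2 coordinates.
#' @param path output path.
#' @param times time labels for the header.
#' @param sep delimiter.
#' @return `path`, invisibly.
#' @export
write_pixel_time_matrix <- function(zmat, coords, path,
                                    times = seq_len(ncol(zmat)),
                                    sep = ",") {
  df <- data.frame(x = coords[, 1], y = coords[, 2], zmat,
                   check.names = FALSE)
  names(df) <- c("x", "y", times)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Machine-readable report for a test result
#'
#' Flattens a test result (plus model/seed metadata) into a named list and
#' optionally writes it as JSON; a run is reproducible from the report plus
#' the input file.
#'
#' @param test a test-result object ([f_test()], [combined_lrt()], ...).
#' @param path optional JSON output path.
#' @param ... extra metadata fields (seeds, model parameters, inputs).
#' @return the report list, invisibly when written.
#' @export
test_report <- function(test, path = NULL, ...) {
  rep_ <- c(unclass(test)[!vapply(unclass(test), is.null, TRUE)],
            list(...))
  if (!is.null(path)) {
    jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep_))
  }
  rep_
}
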