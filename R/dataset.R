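#' Discrete dataset
#'
#' Wraps an `N x n` table of integer-coded states (codes `0..cardinality-1`)
#' together with per-variable cardinalities. Accepts a data frame or matrix
#' of integer codes; factors are converted to 0-based codes in level order.
#' Cardinalities default to `max(code) + 1` per column but should be given
#' explicitly when a small sample may not exercise every state.
#'
#' @param x data frame or matrix of integer state codes (or factors).
#' @param cardinalities optional integer vector of state counts per column.
#' @return a `discrete_dataset`: list with `values` (integer matrix),
#'   `N`, `n`, `names`, `cardinalities`.
#' @export
as_discrete_dataset <- function(x, cardinalities = NULL) {
  if (inherits(x, "discrete_dataset")) return(x)
  if (is.data.frame(x)) {
    x[] <- lapply(x, function(col) {
      if (is.factor(col)) as.integer(col) - 1L else as.integer(col)
    })
    values <- as.matrix(x)
  } else {
    values <- apply(x, 2L, as.integer)
  }
  if (nrow(values) < 1L) stop("dataset needs at least one row", call. = FALSE)
  if (anyNA(values) || any(values < 0L))
    stop("state codes must be non-negative integers without NA", call. = FALSE)
  nms <- colnames(values)
  if (is.null(nms)) nms <- paste0("X", seq_len(ncol(values)))
  if (is.null(cardinalities)) {
    cardinalities <- apply(values, 2L, max) + 1L
    cardinalities <- pmax(cardinalities, 2L)
  }
  cardinalities <- as.integer(cardinalities)
  if (any(cardinalities < 2L)) stop("cardinalities must be >= 2", call. = FALSE)
  for (j in seq_len(ncol(values))) {
    if (any(values[, j] >= cardinalities[j]))
      stop("state code out of range in column ", nms[j], call. = FALSE)
  }
  structure(list(values = unname(values), N = nrow(values), n = ncol(values),
                 names = nms, cardinalities = cardinalities),
            class = "discrete_dataset")
}

#' Read / write a discrete dataset as CSV
#'
#' The dialect is a header row of variable names followed by integer state
#' codes, comma-separated, UTF-8.
#'
#' @param path file path.
#' @param cardinalities optional explicit cardinalities (recommended when a
#'   small file may not show every state).
#' @return `read_discrete_csv()`: a `discrete_dataset`.
#' @export
read_discrete_csv <- function(path, cardinalities = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  as_discrete_dataset(df, cardinalities)
}

#' @rdname read_discrete_csv
#' @param data a `discrete_dataset` or coercible table.
#' @export
write_discrete_csv <- function(data, path) {
  data <- as_discrete_dataset(data)
  df <- as.data.frame(data$values)
  names(df) <- data$names
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat("<discrete_dataset> ", x$N, " samples x ", x$n, " variables\n", sep = "")
  invisible(x)
}
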