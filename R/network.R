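#' Discrete Bayesian network (structure + conditional probability tables)
#'
#' A `bayesian_network` couples a [new_dag()] structure with one CPT per
#' variable. Each CPT is a `q x r` matrix: `r` is the child's cardinality
#' and `q` the product of its parents' cardinalities. Rows index parent
#' configurations in mixed-radix order with the *lowest* parent index as the
#' most significant digit; each row sums to 1.
#'
#' @param structure a `bn_dag`.
#' @param cpts list of CPT matrices, one per variable (in variable order).
#' @param cardinalities integer vector of state counts per variable.
#' @return a `bayesian_network` object.
#' @export
bayesian_network <- function(structure, cpts, cardinalities) {
  stopifnot(inherits(structure, "bn_dag"))
  n <- structure$n
  cardinalities <- as.integer(cardinalities)
  stopifnot(length(cpts) == n, length(cardinalities) == n,
            all(cardinalities >= 2L))
  for (i in seq_len(n)) {
    pa <- decode_subset(structure$parents[i], n)
    q <- prod(cardinalities[pa + 1L])
    r <- cardinalities[i]
    m <- cpts[[i]]
    if (!is.matrix(m) || nrow(m) != q || ncol(m) != r)
      stop("CPT for ", structure$names[i], " must be ", q, " x ", r, call. = FALSE)
    if (any(abs(rowSums(m) - 1) > 1e-9))
      stop("CPT rows for ", structure$names[i], " must sum to 1", call. = FALSE)
  }
  structure(list(structure = structure, cpts = cpts,
                 cardinalities = cardinalities),
            class = "bayesian_network")
}

# row index (1-based) into a CPT for given parent states (0-based codes),
# mixed radix, most significant digit = lowest parent index
cpt_row_index <- function(parent_idx, parent_states, cardinalities) {
  if (length(parent_idx) == 0L) return(1L)
  ord <- order(parent_idx)
  idx <- 0L
  for (k in ord) {
    idx <- idx * cardinalities[parent_idx[k] + 1L] + parent_states[k]
  }
  idx + 1L
}

#' @export
print.bayesian_network <- function(x, ...) {
  cat("<bayesian_network> ", x$structure$n, " variables, ",
      sum(mask_size(x$structure$parents, x$structure$n)), " edges\n", sep = "")
  invisible(x)
}

#' Read / write a network fixture as JSON
#'
#' Format: `variables` is a list of `{name, cardinality}`, `edges` a list of
#' `[parent_name, child_name]` pairs, and the optional `cpts` object maps a
#' child name to its row-major CPT (list of rows, in the package's
#' mixed-radix parent-configuration order).
#'
#' @param path file path.
#' @return `read_network_json()`: a `bayesian_network` when CPTs are present,
#'   otherwise a `bn_dag`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nms <- vapply(obj$variables, function(v) v$name, character(1))
  cards <- vapply(obj$variables, function(v) as.integer(v$cardinality), integer(1))
  n <- length(nms)
  parents <- integer(n)
  for (e in obj$edges) {
    p <- match(e[[1]], nms); c_ <- match(e[[2]], nms)
    if (is.na(p) || is.na(c_))
      stop("edge references unknown variable: ", e[[1]], " -> ", e[[2]], call. = FALSE)
    parents[c_] <- bitwOr(parents[c_], mask_bit(p - 1L))
  }
  g <- new_dag(parents, nms)
  if (is.null(obj$cpts)) return(g)
  cpts <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- obj$cpts[[nms[i]]]
    if (is.null(rows)) stop("missing CPT for ", nms[i], call. = FALSE)
    cpts[[i]] <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  }
  bayesian_network(g, cpts, cards)
}

#' @rdname read_network_json
#' @param x a `bayesian_network` or `bn_dag`.
#' @export
write_network_json <- function(x, path) {
  if (inherits(x, "bayesian_network")) {
    g <- x$structure; cards <- x$cardinalities; cpts <- x$cpts
  } else {
    g <- x; cards <- rep(2L, g$n); cpts <- NULL
  }
  e <- tidy.bn_dag(g)
  obj <- list(
    variables = lapply(seq_len(g$n), function(i)
      list(name = g$names[i], cardinality = cards[i])),
    edges = lapply(seq_len(nrow(e)), function(k) list(e$from[k], e$to[k]))
  )
  if (!is.null(cpts)) {
    obj$cpts <- setNames(lapply(cpts, function(m)
      lapply(seq_len(nrow(m)), function(r) as.numeric(m[r, ]))), g$names)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
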