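#' Directed acyclic graph over a discrete variable domain
#'
#' A `bn_dag` stores one parent-set bitmask per variable (see
#' [encode_subset()]). Construction verifies acyclicity and that no variable
#' is its own parent.
#'
#' @param parent_masks integer vector, one subset mask per variable giving
#'   its parents.
#' @param names character vector of variable names (unique, non-empty);
#'   defaults to `X1..Xn`.
#' @return a `bn_dag` object.
#' @examples
#' g <- new_dag(c(0L, 1L, 2L))       # X1 -> X2 -> X3
#' dag_ancestor_masks(g)[3]          # 3: ancestors of X3 are {X1, X2}
#' @export
new_dag <- function(parent_masks, names = NULL) {
  n <- length(parent_masks)
  parent_masks <- as.integer(parent_masks)
  if (is.null(names)) names <- paste0("X", seq_len(n))
  if (length(names) != n || anyDuplicated(names) || any(!nzchar(names)))
    stop("variable names must be unique and non-empty", call. = FALSE)
  for (i in seq_len(n)) {
    if (mask_has(parent_masks[i], i - 1L))
      stop("variable ", names[i], " listed as its own parent", call. = FALSE)
  }
  if (!is_acyclic(parent_masks))
    stop("parent sets contain a directed cycle", call. = FALSE)
  structure(list(n = n, parents = parent_masks, names = names),
            class = "bn_dag")
}

#' Test a set of parent masks for acyclicity
#'
#' True iff a topological order exists, decided by repeated leaf-stripping:
#' a variable whose parents all lie outside the remaining set can be removed;
#' the graph is acyclic iff everything can be removed.
#'
#' @param parent_masks integer vector of parent-set masks.
#' @return logical scalar.
#' @export
is_acyclic <- function(parent_masks) {
  n <- length(parent_masks)
  remaining <- encode_subset(seq_len(n) - 1L, n)
  repeat {
    if (remaining == 0L) return(TRUE)
    progressed <- FALSE
    for (i in seq_len(n) - 1L) {
      if (mask_has(remaining, i) &&
          bitwAnd(parent_masks[i + 1L], remaining) == 0L) {
        remaining <- bitwAnd(remaining, bitwNot(mask_bit(i)))
        progressed <- TRUE
      }
    }
    if (!progressed) return(FALSE)
  }
}

# topological order of a bn_dag (0-based indices), parents before children
topo_order <- function(parent_masks, n) {
  order <- integer(0)
  placed <- 0L
  remaining <- encode_subset(seq_len(n) - 1L, n)
  while (remaining != 0L) {
    progressed <- FALSE
    for (i in seq_len(n) - 1L) {
      if (mask_has(remaining, i) && bitwAnd(parent_masks[i + 1L], bitwNot(placed)) == 0L) {
        order <- c(order, i)
        placed <- bitwOr(placed, mask_bit(i))
        remaining <- bitwAnd(remaining, bitwNot(mask_bit(i)))
        progressed <- TRUE
      }
    }
    if (!progressed) stop("cycle detected in topo_order", call. = FALSE)
  }
  order
}

#' Ancestor masks (transitive closure) of a DAG
#'
#' Returns, for each variable, the bitmask of all its ancestors: variable
#' `X` is in the mask of `Y` iff a directed path `X => Y` exists. The
#' descendant relation is the transpose, available via
#' `dag_descendant_masks()`.
#'
#' @param g a [new_dag()] object.
#' @return integer vector of ancestor masks, one per variable.
#' @export
dag_ancestor_masks <- function(g) {
  stopifnot(inherits(g, "bn_dag"))
  anc <- integer(g$n)
  for (i in topo_order(g$parents, g$n)) {
    pa <- decode_subset(g$parents[i + 1L], g$n)
    a <- g$parents[i + 1L]
    for (p in pa) a <- bitwOr(a, anc[p + 1L])
    anc[i + 1L] <- a
  }
  anc
}

#' @rdname dag_ancestor_masks
#' @export
dag_descendant_masks <- function(g) {
  anc <- dag_ancestor_masks(g)
  des <- integer(g$n)
  for (y in seq_len(g$n) - 1L) {
    for (x in decode_subset(anc[y + 1L], g$n)) {
      des[x + 1L] <- bitwOr(des[x + 1L], mask_bit(y))
    }
  }
  des
}

#' Root and leaf views of a DAG
#'
#' Roots are variables with an empty parent set; leaves are variables that
#' appear in no parent set.
#'
#' @param g a [new_dag()] object.
#' @return integer mask of the root (resp. leaf) variables.
#' @export
dag_roots <- function(g) {
  encode_subset(which(g$parents == 0L) - 1L, g$n)
}

#' @rdname dag_roots
#' @export
dag_leaves <- function(g) {
  all_parents <- Reduce(bitwOr, g$parents, 0L)
  encode_subset(which(bitwAnd(all_parents, bitwShiftL(1L, seq_len(g$n) - 1L)) == 0L) - 1L,
                g$n)
}

#' @export
print.bn_dag <- function(x, ...) {
  ne <- sum(mask_size(x$parents, x$n))
  cat("<bn_dag> ", x$n, " variables, ", ne, " edges\n", sep = "")
  invisible(x)
}

#' Edge list of a DAG as a tibble
#'
#' @param x a `bn_dag`.
#' @param ... unused.
#' @return a tibble with columns `from`, `to` (variable names).
#' @importFrom generics tidy
#' @export
tidy.bn_dag <- function(x, ...) {
  from <- character(0); to <- character(0)
  for (i in seq_len(x$n)) {
    for (p in decode_subset(x$parents[i], x$n)) {
      from <- c(from, x$names[p + 1L]); to <- c(to, x$names[i])
    }
  }
  tibble::tibble(from = from, to = to)
}

#' Export a DAG to Graphviz DOT or a two-column TSV edge list
#'
#' @param g a `bn_dag`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(g, path) {
  e <- tidy.bn_dag(g)
  lines <- c("digraph bn {",
             paste0("  \"", g$names, "\";"),
             if (nrow(e)) paste0("  \"", e$from, "\" -> \"", e$to, "\";"),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dot
#' @export
write_edge_tsv <- function(g, path) {
  e <- tidy.bn_dag(g)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
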