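#' Exhaustive search over all DAGs (validation oracle)
#'
#' Enumerates every labelled DAG on `n <= 5` nodes (25 for n = 3, 543 for
#' n = 4, 29281 for n = 5), discards those violating the constraint set
#' (edges directly, paths via the transitive closure), and returns a
#' maximum-score survivor under the given score cache. Deliberately
#' independent of the dynamic program: enumeration by brute force over all
#' parent-set combinations with vectorised leaf-elimination acyclicity
#' filtering.
#'
#' @param cache a [compute_score_cache()] result with `nmp >= n - 1` (the
#'   oracle considers every parent set; smaller caches restrict it to the
#'   same families the DP can reach, which is the comparable setting).
#' @param cs a [constraint_set()].
#' @param n domain size, at most 5.
#' @return list with `dag`, `score`, and `n_dags` considered; errors if no
#'   DAG satisfies the constraints.
#' @export
exhaustive_best_dag <- function(cache, cs, n) {
  stopifnot(n >= 1L, n <= 5L)
  dags <- all_dags(n)   # matrix: one row per DAG, column j = parent mask of Xj
  # score every DAG under the cache; families outside the cached bound get -Inf
  total <- rep(0, nrow(dags))
  for (j in seq_len(n)) {
    s <- cache$scores[[j]][dags[, j] + 1L]
    s[is.na(s)] <- -Inf
    total <- total + s
  }
  keep <- rep(TRUE, nrow(dags))
  e <- cs$edges
  for (k in seq_len(nrow(e))) {
    has <- bitwAnd(dags[, e$to[k] + 1L], mask_bit(e$from[k])) != 0L
    keep <- keep & (if (e$required[k]) has else !has)
  }
  if (nrow(cs$paths)) {
    anc <- all_dag_ancestors(dags, n)
    p <- cs$paths
    for (k in seq_len(nrow(p))) {
      has <- bitwAnd(anc[, p$to[k] + 1L], mask_bit(p$from[k])) != 0L
      keep <- keep & (if (p$required[k]) has else !has)
    }
  }
  keep <- keep & is.finite(total)
  if (!any(keep)) stop("no DAG satisfies the constraints", call. = FALSE)
  idx <- which(keep)
  best <- idx[which.max(total[idx])]
  list(dag = new_dag(dags[best, ], cache$names), score = total[best],
       n_dags = nrow(dags))
}

# all labelled DAGs on n nodes as a matrix of parent masks, memoised
all_dags <- function(n) {
  key <- paste0("dags", n)
  if (!is.null(the[[key]])) return(the[[key]])
  allowed <- lapply(seq_len(n), function(j) {
    m <- 0:(2^n - 1)
    m[bitwAnd(m, mask_bit(j - 1L)) == 0L]   # no self-parenthood
  })
  combos <- as.matrix(expand.grid(allowed))
  # vectorised leaf elimination: repeatedly remove variables whose parents
  # all lie outside the remaining set; acyclic iff everything is removed
  remaining <- rep(encode_subset(seq_len(n) - 1L, n), nrow(combos))
  for (pass in seq_len(n)) {
    for (j in seq_len(n)) {
      can_drop <- bitwAnd(remaining, mask_bit(j - 1L)) != 0L &
        bitwAnd(combos[, j], remaining) == 0L
      remaining[can_drop] <- bitwAnd(remaining[can_drop],
                                     bitwNot(mask_bit(j - 1L)))
    }
  }
  out <- combos[remaining == 0L, , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  the[[key]] <- out
  out
}

# ancestor masks for every DAG in an all_dags matrix, vectorised:
# iterate anc_j = pa_j | union of anc_i over parents i until fixpoint
all_dag_ancestors <- function(dags, n) {
  anc <- dags
  for (pass in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- anc[, j]
      for (i in seq_len(n)) {
        if (i == j) next
        has_i <- bitwAnd(dags[, j], mask_bit(i - 1L)) != 0L
        a[has_i] <- bitwOr(a[has_i], anc[has_i, i])
      }
      anc[, j] <- a
    }
  }
  anc
}
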