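#' Layered dynamic program over the order graph
#'
#' The order graph is the Hasse diagram of variable subsets: an entry for
#' subset `U` holds the best total score of any DAG over exactly the
#' variables `U`. Layer `k+1` is produced by extending every admitted
#' subset `u` with every admissible variable `X` ([allowed_extensions()]),
#' scoring `X`'s best constrained parent set within `u` via the sparse
#' parent graph queries, and keeping the maximum route into each resulting
#' subset. The full-set entry backtraces to the optimal DAG.
#'
#' @param spgs list of [sparse_parent_graph] objects, one per child, built
#'   in the mode matching the constraint set (see [build_parent_graphs()]).
#' @param cs a consistent [constraint_set()] (may be empty).
#' @param n domain size.
#' @param names optional variable names for the returned DAG.
#' @return list with `dag` (a `bn_dag`), `score`, `layer_sizes` (admitted
#'   entries per layer, the planning-space trace) and `engine` internals.
#' @export
dp_learn <- function(spgs, cs, n, names = NULL) {
  gc <- build_constraint_graph(cs)
  path_mode <- has_path_constraints(cs)
  e <- cs$edges
  req_pa <- vapply(seq_len(n) - 1L, function(ch)
    encode_subset(e$from[e$required & e$to == ch], n), integer(1))
  forb_pa <- vapply(seq_len(n) - 1L, function(ch)
    encode_subset(e$from[!e$required & e$to == ch], n), integer(1))
  p <- cs$paths
  req_anc <- lapply(seq_len(n) - 1L, function(ch) p$from[p$required & p$to == ch])
  forb_anc <- lapply(seq_len(n) - 1L, function(ch) p$from[!p$required & p$to == ch])

  size <- bitwShiftL(1L, n)
  score <- rep(-Inf, size)
  last <- rep(-1L, size)
  par <- rep(-1L, size)
  score[1L] <- 0
  layer <- 0L            # masks in the current layer
  layer_sizes <- integer(0)
  full <- encode_subset(seq_len(n) - 1L, n)

  for (k in seq_len(n)) {
    nxt <- integer(0)
    for (u in layer) {
      if (!is.finite(score[u + 1L])) next
      ext <- decode_subset(allowed_extensions(u, gc, n), n)
      if (!length(ext)) next
      des <- NULL
      if (path_mode) {
        g_u <- dp_substructure(u, last, par, n)
        des <- dag_descendant_masks_raw(g_u, n)
      }
      for (x in ext) {
        if (path_mode && (length(req_anc[[x + 1L]]) || length(forb_anc[[x + 1L]]))) {
          q <- query_best_parents_path(spgs[[x + 1L]], u,
                                       required_anc = req_anc[[x + 1L]],
                                       forbidden_anc = forb_anc[[x + 1L]],
                                       des_masks = des,
                                       required = req_pa[x + 1L],
                                       forbidden = forb_pa[x + 1L])
        } else {
          q <- query_best_parents_edge(spgs[[x + 1L]], u,
                                       required = req_pa[x + 1L],
                                       forbidden = forb_pa[x + 1L])
        }
        if (is.null(q)) next  # infeasible extension under the constraints
        v <- bitwOr(u, mask_bit(x))
        cur <- score[u + 1L] + q$score
        if (!is.finite(score[v + 1L])) {
          nxt <- c(nxt, v)
          score[v + 1L] <- cur; last[v + 1L] <- x; par[v + 1L] <- q$mask
        } else if (cur > score[v + 1L] ||
                   (cur == score[v + 1L] &&
                    (x < last[v + 1L] ||
                     (x == last[v + 1L] && q$mask < par[v + 1L])))) {
          score[v + 1L] <- cur; last[v + 1L] <- x; par[v + 1L] <- q$mask
        }
      }
    }
    layer <- nxt
    layer_sizes <- c(layer_sizes, length(layer))
  }
  if (!is.finite(score[full + 1L])) {
    blocked <- which(layer_sizes == 0L)[1]
    stop("no structure satisfies the constraints (order graph empty at layer ",
         blocked, ")", call. = FALSE)
  }
  parents <- dp_substructure(full, last, par, n)
  list(dag = new_dag(parents, names), score = score[full + 1L],
       layer_sizes = layer_sizes,
       engine = list(score = score, last = last, par = par, n = n))
}

# reconstruct the parent masks of the best substructure over subset u by
# walking backpointers; variables outside u get empty parents
dp_substructure <- function(u, last, par, n) {
  parents <- integer(n)
  m <- u
  while (m != 0L) {
    x <- last[m + 1L]
    if (x < 0L) stop("broken backpointer chain at mask ", m, call. = FALSE)
    parents[x + 1L] <- par[m + 1L]
    m <- bitwAnd(m, bitwNot(mask_bit(x)))
  }
  parents
}

# descendant masks from raw parent masks (no bn_dag validation; DP-internal)
dag_descendant_masks_raw <- function(parents, n) {
  des <- integer(n)
  for (i in topo_order(parents, n)) {
    for (p in decode_subset(parents[i + 1L], n)) {
      des[p + 1L] <- bitwOr(des[p + 1L], bitwOr(mask_bit(i), des[i + 1L]))
    }
  }
  # one backward pass is not enough for deep chains; iterate to fixpoint
  repeat {
    changed <- FALSE
    for (i in seq_len(n) - 1L) {
      for (p in decode_subset(parents[i + 1L], n)) {
        upd <- bitwOr(des[p + 1L], bitwOr(mask_bit(i), des[i + 1L]))
        if (upd != des[p + 1L]) { des[p + 1L] <- upd; changed <- TRUE }
      }
    }
    if (!changed) return(des)
  }
}

#' Reconstruct the best substructure over a subset
#'
#' Walks the backpointers stored by [dp_learn()] from the entry of `u`,
#' yielding each placed variable's chosen parent set. Needed on demand by
#' path-constrained queries (descendant relations in `g_u`).
#'
#' @param engine the `engine` element of a [dp_learn()] result.
#' @param u subset mask.
#' @return a `bn_dag` over the full domain with empty parents outside `u`.
#' @export
reconstruct_structure <- function(engine, u) {
  new_dag(dp_substructure(u, engine$last, engine$par, engine$n))
}

#' Size of the constraint-pruned order graph
#'
#' Counts the non-empty subsets admitted by the required-ancestry pruning
#' rule — the planning space of the dynamic program. A subset is admitted
#' iff it is "ancestor-closed" under the transitive closure of the required
#' relations; unconstrained variables are free, so the count factorises as
#' `(closed subsets of the constrained block) * 2^(n - |constrained|) - 1`.
#' With no required constraints this is `2^n - 1`.
#'
#' @param n domain size.
#' @param cs a consistent [constraint_set()].
#' @return integer-valued count (as double; may exceed 2^31).
#' @examples
#' count_order_graph_entries(18, empty_constraints(paste0("X", 1:18)))  # 262143
#' @export
count_order_graph_entries <- function(n, cs) {
  req <- required_relations(cs)
  if (nrow(req) == 0L) return(2^n - 1)
  gc <- build_constraint_graph(cs)
  anc <- dag_ancestor_masks(new_dag(gc$parents, cs$names))
  cvars <- decode_subset(gc$var_mask, n)
  k <- length(cvars)
  sub <- 0:(2^k - 1)            # subsets of the constrained block
  ok <- rep(TRUE, length(sub))
  for (j in seq_along(cvars)) {
    y <- cvars[j]
    a <- anc[y + 1L]                         # required ancestors of y
    abits <- match(decode_subset(a, n), cvars)   # positions within block
    if (!length(abits)) next
    need <- sum(bitwShiftL(1L, abits - 1L))
    has_y <- bitwAnd(sub, bitwShiftL(1L, j - 1L)) != 0L
    ok <- ok & (!has_y | bitwAnd(sub, need) == need)
  }
  sum(ok) * 2^(n - k) - 1
}
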