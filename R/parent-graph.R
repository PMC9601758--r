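#' Sparse parent graphs: pruned, score-sorted candidate parent sets
#'
#' For each child, the sparse parent graph (SPG) stores candidate parent
#' sets in descending score order (ties broken by smaller mask) alongside
#' per-variable membership bit arrays: bit `t` of `membership[[Y]]` is 1 iff
#' stored set `t` contains variable `Y`. Best-parent-set queries are then a
#' handful of AND/AND-NOT operations over these arrays followed by a
#' first-set-bit scan.
#'
#' Three construction modes exist:
#' * *unconstrained* — dominance pruning: a set is stored only if its score
#'   strictly beats every stored proper subset's best score;
#' * *edge-pruned* — additionally, no stored set contains a forbidden parent
#'   of the child, and dominance propagation never removes a required
#'   parent, so comparison chains through the required parents survive;
#' * *full* — every parent set up to the parent bound is stored unpruned
#'   (used for path-constraint tail nodes, whose admissible sets depend on
#'   the run-time substructure and cannot be pruned in advance).
#'
#' @name sparse_parent_graph
NULL

new_spg <- function(child, masks, scores, n, mode) {
  ord <- order(-scores, masks)
  masks <- as.integer(masks[ord]); scores <- scores[ord]
  membership <- lapply(seq_len(n) - 1L, function(v) {
    bitwAnd(masks, mask_bit(v)) != 0L
  })
  structure(list(child = child, masks = masks, scores = scores,
                 membership = membership, n = n, mode = mode),
            class = "sparse_parent_graph")
}

#' @export
print.sparse_parent_graph <- function(x, ...) {
  cat("<sparse_parent_graph> child ", x$child, ", ", length(x$masks),
      " stored sets, mode '", x$mode, "'\n", sep = "")
  invisible(x)
}

#' Build the unconstrained sparse parent graph of one child
#'
#' Stores exactly the parent sets whose score strictly improves on the best
#' score of every proper subset; for every candidate superset query the top
#' surviving stored set then attains the optimum.
#'
#' @param cache a [compute_score_cache()] result.
#' @param child 0-based child index.
#' @return a `sparse_parent_graph` (mode `"unconstrained"`).
#' @export
build_spg_unconstrained <- function(cache, child) {
  spg_build_pruned(cache, child, required = 0L, forbidden = 0L,
                   mode = "unconstrained")
}

#' Build the edge-constrained sparse parent graph of one child
#'
#' As the unconstrained build, except sets containing a forbidden parent of
#' the child are never stored, and the dominance recursion only removes
#' non-required variables, so required parents are retained along every
#' comparison chain.
#'
#' @param cache a `score_cache`.
#' @param child 0-based child index.
#' @param cs a consistent [constraint_set()].
#' @return a `sparse_parent_graph` (mode `"edge"`).
#' @export
build_spg_edge <- function(cache, child, cs) {
  e <- cs$edges
  required <- encode_subset(e$from[e$required & e$to == child], cache$n)
  forbidden <- encode_subset(e$from[!e$required & e$to == child], cache$n)
  spg_build_pruned(cache, child, required, forbidden, mode = "edge")
}

# shared dominance-pruned construction; `required` parents are never removed
# by the pruning recursion and `forbidden` parents exclude a set entirely
spg_build_pruned <- function(cache, child, required, forbidden, mode) {
  n <- cache$n
  full <- encode_subset(seq_len(n) - 1L, n)
  ground <- bitwAnd(full, bitwNot(bitwOr(mask_bit(child), forbidden)))
  cand <- subsets_up_to(ground, n, cache$nmp)  # popcount-ascending
  best <- rep(-Inf, bitwShiftL(1L, n))
  keep_mask <- integer(0); keep_score <- numeric(0)
  for (m in cand) {
    sub_best <- -Inf
    removable <- bitwAnd(m, bitwNot(required))
    for (y in decode_subset(removable, n)) {
      b <- best[bitwAnd(m, bitwNot(mask_bit(y))) + 1L]
      if (b > sub_best) sub_best <- b
    }
    s <- cache$scores[[child + 1L]][m + 1L]
    if (!is.na(s) && s > sub_best) {
      keep_mask <- c(keep_mask, m); keep_score <- c(keep_score, s)
      best[m + 1L] <- s
    } else {
      best[m + 1L] <- sub_best
    }
  }
  new_spg(child, keep_mask, keep_score, n, mode)
}

#' Build the path-mode sparse parent graph of one child
#'
#' A child that is the tail of any path constraint gets the *full* table:
#' every parent set of size at most the parent bound, unpruned, because
#' which sets are admissible depends on descendant relations in the
#' substructure current at query time. Any other child gets the
#' unconstrained dominance-pruned table.
#'
#' @inheritParams build_spg_edge
#' @return a `sparse_parent_graph` (mode `"full"` or `"unconstrained"`).
#' @export
build_spg_path <- function(cache, child, cs) {
  tails <- unique(cs$paths$to)
  if (!(child %in% tails)) return(build_spg_unconstrained(cache, child))
  n <- cache$n
  full <- encode_subset(seq_len(n) - 1L, n)
  ground <- bitwAnd(full, bitwNot(mask_bit(child)))
  cand <- subsets_up_to(ground, n, cache$nmp)
  scores <- cache$scores[[child + 1L]][cand + 1L]
  new_spg(child, cand, scores, n, "full")
}

#' Best parent set under edge (direct-parent) query constraints
#'
#' Bitvector query: start from an all-ones validity array over the stored
#' sets; AND in the membership row of every required parent; AND in the
#' complement rows of every variable outside the candidate superset `u` and
#' of every forbidden parent; the first surviving set (highest score) is
#' the constrained optimum.
#'
#' @param spg a `sparse_parent_graph` for the child.
#' @param u subset mask of allowed candidate parents (the placed variables).
#' @param required mask of required parents (must be within `u`).
#' @param forbidden mask of forbidden parents (disjoint from `required`).
#' @return list with `mask`, `score`, and the logical `valid` array; or
#'   `NULL` when no stored set satisfies the constraints (infeasible query
#'   — the caller treats that extension as inadmissible).
#' @export
query_best_parents_edge <- function(spg, u, required = 0L, forbidden = 0L) {
  n <- spg$n
  if (bitwAnd(required, bitwNot(u)) != 0L)
    stop("required parents must lie within u", call. = FALSE)
  if (bitwAnd(required, forbidden) != 0L)
    stop("required and forbidden parents overlap", call. = FALSE)
  valid <- rep(TRUE, length(spg$masks))
  for (y in decode_subset(bitwAnd(required, u), n))
    valid <- valid & spg$membership[[y + 1L]]
  full <- encode_subset(seq_len(n) - 1L, n)
  outside <- bitwOr(bitwAnd(full, bitwNot(u)), forbidden)
  for (y in decode_subset(outside, n))
    valid <- valid & !spg$membership[[y + 1L]]
  i <- which(valid)[1]
  if (is.na(i)) return(NULL)
  list(mask = spg$masks[i], score = spg$scores[i], valid = valid)
}

#' Best parent set under path (ancestral) query constraints
#'
#' For every required ancestor `X` of the child, the chosen parent set must
#' intersect `{X} union descendants(X)` taken in the current best
#' substructure over `u` — otherwise no directed path from `X` could reach
#' the child. For every forbidden ancestor present in `u`, the parent set
#' must avoid that closure entirely. Implemented as OR-accumulated
#' `Cvalid` arrays ANDed into the validity array.
#'
#' @param spg a `sparse_parent_graph` for the child (mode `"full"` if the
#'   child is a path tail).
#' @param u subset mask of placed variables.
#' @param required_anc 0-based indices of required ancestors of the child
#'   (all must be in `u`).
#' @param forbidden_anc 0-based indices of forbidden ancestors.
#' @param des_masks integer vector: descendant mask per variable in the best
#'   substructure over `u` (from [dag_descendant_masks()] of `g_u`).
#' @param required,forbidden masks of required / forbidden *direct* parents,
#'   applied as in [query_best_parents_edge()] (for children carrying both
#'   edge and path constraints).
#' @return as [query_best_parents_edge()]; additionally `cvalids`, the list
#'   of per-required-ancestor OR arrays.
#' @export
query_best_parents_path <- function(spg, u, required_anc = integer(0),
                                    forbidden_anc = integer(0), des_masks = NULL,
                                    required = 0L, forbidden = 0L) {
  n <- spg$n
  valid <- rep(TRUE, length(spg$masks))
  full <- encode_subset(seq_len(n) - 1L, n)
  for (y in decode_subset(bitwAnd(required, u), n))
    valid <- valid & spg$membership[[y + 1L]]
  outside <- bitwOr(bitwAnd(full, bitwNot(u)), forbidden)
  for (y in decode_subset(outside, n))
    valid <- valid & !spg$membership[[y + 1L]]
  cvalids <- list()
  for (x in required_anc) {
    if (!mask_has(u, x))
      stop("required ancestor not yet placed in u", call. = FALSE)
    closure <- bitwOr(mask_bit(x), bitwAnd(des_masks[x + 1L], u))
    cvalid <- rep(FALSE, length(spg$masks))
    for (z in decode_subset(closure, n))
      cvalid <- cvalid | spg$membership[[z + 1L]]
    valid <- valid & cvalid
    cvalids[[length(cvalids) + 1L]] <- cvalid
  }
  for (x in forbidden_anc) {
    if (!mask_has(u, x)) next  # outside u: cannot be an ancestor of the child
    closure <- bitwOr(mask_bit(x), bitwAnd(des_masks[x + 1L], u))
    for (z in decode_subset(closure, n))
      valid <- valid & !spg$membership[[z + 1L]]
  }
  i <- which(valid)[1]
  if (is.na(i)) return(NULL)
  list(mask = spg$masks[i], score = spg$scores[i], valid = valid,
       cvalids = cvalids)
}

#' Build the per-child sparse parent graphs for a whole learning problem
#'
#' Chooses the construction mode per child from the constraint set: path
#' tails get full tables, children with edge constraints get edge-pruned
#' tables, everything else the unconstrained build.
#'
#' @param cache a `score_cache`.
#' @param cs a `constraint_set` (may be empty).
#' @return list of `sparse_parent_graph`, one per variable.
#' @export
build_parent_graphs <- function(cache, cs) {
  lapply(seq_len(cache$n) - 1L, function(child) {
    if (has_path_constraints(cs) && child %in% cs$paths$to) {
      build_spg_path(cache, child, cs)
    } else if (nrow(cs$edges) && any(cs$edges$to == child)) {
      build_spg_edge(cache, child, cs)
    } else {
      build_spg_unconstrained(cache, child)
    }
  })
}
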