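# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no binary fixtures.

# a synthetic score cache with iid normal family scores for every parent
# set up to nmp (independent of any dataset; exercises the search machinery
# on arbitrary score landscapes)
random_score_cache <- function(n, nmp = n - 1L, seed = 1L) {
  set.seed(seed)
  full <- encode_subset(seq_len(n) - 1L, n)
  scores <- lapply(seq_len(n) - 1L, function(child) {
    ground <- bitwAnd(full, bitwNot(bitwShiftL(1L, child)))
    masks <- priordp:::subsets_up_to(ground, n, nmp)
    s <- rep(NA_real_, bitwShiftL(1L, n))
    s[masks + 1L] <- rnorm(length(masks))
    s
  })
  structure(list(scores = scores, n = n, nmp = as.integer(nmp), N = 100L,
                 cardinalities = rep(2L, n), names = paste0("X", seq_len(n))),
            class = "score_cache")
}

# a random DAG as parent masks (upper-triangular in a random permutation)
random_dag_masks <- function(n, p = 0.4, seed = 1L) {
  set.seed(seed)
  perm <- sample.int(n) - 1L
  parents <- integer(n)
  for (jj in 2:n) {
    for (ii in seq_len(jj - 1L)) {
      if (runif(1) < p) {
        child <- perm[jj]; par <- perm[ii]
        parents[child + 1L] <- bitwOr(parents[child + 1L],
                                      bitwShiftL(1L, par))
      }
    }
  }
  parents
}

# a consistent random constraint set derived from a hidden random DAG:
# required relations are true edges (or closure pairs), forbidden relations
# are pairs absent from the closure, so the hidden DAG witnesses
# satisfiability
random_constraints <- function(n, kind = c("edge", "path"), seed = 1L,
                               n_required = 2L, n_forbidden = 2L,
                               max_required_parents = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  nms <- paste0("X", seq_len(n))
  masks <- random_dag_masks(n, p = 0.5, seed = seed + 1000L)
  g <- new_dag(masks, nms)
  anc <- dag_ancestor_masks(g)
  edges <- do.call(rbind, lapply(seq_len(n), function(j) {
    pa <- decode_subset(masks[j], n)
    if (!length(pa)) return(NULL)
    data.frame(from = pa, to = j - 1L)
  }))
  closure <- do.call(rbind, lapply(seq_len(n), function(j) {
    a <- decode_subset(anc[j], n)
    if (!length(a)) return(NULL)
    data.frame(from = a, to = j - 1L)
  }))
  pool <- if (kind == "edge") edges else closure
  req <- NULL
  if (!is.null(pool) && nrow(pool) && n_required > 0L) {
    take <- sample.int(nrow(pool), min(n_required, nrow(pool)))
    req <- cbind(pool[take, ], required = TRUE)
    if (kind == "edge" && !is.null(max_required_parents)) {
      # cap required parents per child so families stay within the bound
      keep <- unlist(lapply(split(seq_len(nrow(req)), req$to), function(i)
        head(i, max_required_parents)))
      req <- req[keep, ]
    }
  }
  # forbidden pairs: ordered pairs absent from the closure
  allp <- expand.grid(from = seq_len(n) - 1L, to = seq_len(n) - 1L)
  allp <- allp[allp$from != allp$to, ]
  in_closure <- mapply(function(f, t) priordp:::mask_has(anc[t + 1L], f),
                       allp$from, allp$to)
  cand <- allp[!in_closure, ]
  forb <- NULL
  if (nrow(cand) && n_forbidden > 0L) {
    take <- sample.int(nrow(cand), min(n_forbidden, nrow(cand)))
    forb <- cbind(cand[take, ], required = FALSE)
  }
  df <- rbind(req, forb)
  if (!is.null(df)) {
    df$from <- nms[df$from + 1L]; df$to <- nms[df$to + 1L]
  }
  if (kind == "edge") {
    constraint_set(edges = df, names = nms)
  } else {
    constraint_set(paths = df, names = nms)
  }
}

# the five-candidate parent table of the edge-constrained query worked
# example (child X3 in a 5-variable domain)
table1_spg <- function() {
  n <- 5L
  masks <- c(encode_subset(c(0, 4), n), encode_subset(c(0, 1, 3), n),
             encode_subset(c(0, 1, 4), n), 0L, encode_subset(0, n))
  priordp:::new_spg(2L, masks, c(5, 4, 3, 2, 1), n, "edge")
}

# the path-constrained worked example: parent table for Y (index 4) plus
# the substructure over {X1..X4} whose descendant relations the query uses
# (des(X1) = {X3}, des(X2) = {X3, X4})
table2_fixture <- function() {
  n <- 5L
  masks <- c(encode_subset(c(1, 3), n), encode_subset(3, n),
             encode_subset(c(2, 3), n), 0L, encode_subset(2, n))
  spg <- priordp:::new_spg(4L, masks, c(5, 4, 3, 2, 1), n, "full")
  pa <- c(0L, 0L, encode_subset(c(0, 1), n), encode_subset(1, n), 0L)
  des <- priordp:::dag_descendant_masks_raw(pa, n)
  list(spg = spg, des = des, u = encode_subset(0:3, n))
}

# linear scan over the sets stored in an SPG with explicit set tests
# (independent of the bitvector machinery)
brute_best_parents_spg <- function(spg, u, required_anc, forbidden_anc, des) {
  n <- spg$n
  best <- NULL
  for (t in seq_along(spg$masks)) {
    m <- spg$masks[t]
    if (bitwAnd(m, bitwNot(u)) != 0L) next
    ok <- TRUE
    for (x in required_anc) {
      closure <- bitwOr(bitwShiftL(1L, x), bitwAnd(des[x + 1L], u))
      if (bitwAnd(m, closure) == 0L) { ok <- FALSE; break }
    }
    if (ok) for (x in forbidden_anc) {
      if (!priordp:::mask_has(u, x)) next
      closure <- bitwOr(bitwShiftL(1L, x), bitwAnd(des[x + 1L], u))
      if (bitwAnd(m, closure) != 0L) { ok <- FALSE; break }
    }
    if (!ok) next
    if (is.null(best) || spg$scores[t] > best$score ||
        (spg$scores[t] == best$score && m < best$mask))
      best <- list(mask = m, score = spg$scores[t])
  }
  best
}

# brute-force constrained best-parent query by linear scan over ALL cached
# parent sets (not just stored ones) with explicit set tests
brute_best_parents <- function(cache, child, u, required = 0L, forbidden = 0L,
                               required_anc = integer(0),
                               forbidden_anc = integer(0), des_masks = NULL) {
  n <- cache$n
  s <- cache$scores[[child + 1L]]
  best <- NULL
  for (m in which(!is.na(s)) - 1L) {
    if (bitwAnd(m, bitwNot(u)) != 0L) next
    if (bitwAnd(m, required) != required) next
    if (bitwAnd(m, forbidden) != 0L) next
    ok <- TRUE
    for (x in required_anc) {
      closure <- bitwOr(bitwShiftL(1L, x), bitwAnd(des_masks[x + 1L], u))
      if (bitwAnd(m, closure) == 0L) { ok <- FALSE; break }
    }
    if (ok) for (x in forbidden_anc) {
      if (!priordp:::mask_has(u, x)) next
      closure <- bitwOr(bitwShiftL(1L, x), bitwAnd(des_masks[x + 1L], u))
      if (bitwAnd(m, closure) != 0L) { ok <- FALSE; break }
    }
    if (!ok) next
    if (is.null(best) || s[m + 1L] > best$score ||
        (s[m + 1L] == best$score && m < best$mask))
      best <- list(mask = m, score = s[m + 1L])
  }
  best
}
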