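#' Random ground-truth Bayesian network
#'
#' Samples a DAG edge-wise in the fixed topological order of the variable
#' indices (an edge `i -> j`, `i < j`, is present with probability
#' `edge_prob`) and fills each CPT row with a draw from a symmetric
#' Dirichlet. The same seed reproduces the network bit-exactly.
#'
#' Defaults emulate sparse benchmark-like networks: `edge_prob = 0.3`
#' (about `0.15 * n * (n-1) / 2` edges), binary variables, and
#' `dirichlet_alpha = 0.5`, which favours skewed conditional distributions
#' of the kind the classic benchmark networks exhibit (near-deterministic
#' relations), so that structure is identifiable from moderate samples.
#'
#' @param n variable count.
#' @param edge_prob per-pair edge probability in topological order.
#' @param cardinality states per variable (scalar or vector).
#' @param dirichlet_alpha symmetric Dirichlet concentration for CPT rows.
#' @param seed integer seed.
#' @return a [bayesian_network()].
#' @export
random_network <- function(n, edge_prob = 0.3, cardinality = 2L,
                           dirichlet_alpha = 0.5, seed = 1L) {
  stopifnot(edge_prob >= 0, edge_prob <= 1, n >= 1)
  cards <- as.integer(rep_len(cardinality, n))
  stopifnot(all(cards >= 2L))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  parents <- integer(n)
  if (n >= 2L) {
    for (j in 2:n) {
      for (i in seq_len(j - 1L)) {
        if (runif(1) < edge_prob)
          parents[j] <- bitwOr(parents[j], mask_bit(i - 1L))
      }
    }
  }
  g <- new_dag(parents)
  cpts <- lapply(seq_len(n), function(i) {
    pa <- decode_subset(parents[i], n)
    q <- if (length(pa)) prod(cards[pa + 1L]) else 1L
    r <- cards[i]
    m <- matrix(rgamma(q * r, shape = dirichlet_alpha), nrow = q)
    m / rowSums(m)
  })
  bayesian_network(g, cpts, cards)
}

#' Forward (ancestral) sampling from a Bayesian network
#'
#' Draws each variable given its sampled parents, visiting variables in a
#' topological order, so empirical frequencies converge to the network's
#' distribution as `N` grows.
#'
#' @param bn a [bayesian_network()].
#' @param N number of samples.
#' @param seed integer seed.
#' @return a [as_discrete_dataset()] with `N` rows.
#' @export
forward_sample <- function(bn, N, seed = 1L) {
  stopifnot(inherits(bn, "bayesian_network"), N >= 1)
  g <- bn$structure; n <- g$n; cards <- bn$cardinalities
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  values <- matrix(0L, nrow = N, ncol = n)
  for (i in topo_order(g$parents, n)) {
    pa <- decode_subset(g$parents[i + 1L], n)
    cpt <- bn$cpts[[i + 1L]]
    if (length(pa) == 0L) {
      values[, i + 1L] <- sample.int(cards[i + 1L], N, replace = TRUE,
                                     prob = cpt[1L, ]) - 1L
    } else {
      cfg <- integer(N)
      for (p in pa) cfg <- cfg * cards[p + 1L] + values[, p + 1L]
      u <- runif(N)
      cum <- t(apply(cpt, 1L, cumsum))
      row_u <- cum[cfg + 1L, , drop = FALSE]
      values[, i + 1L] <- pmin(as.integer(rowSums(u > row_u)),
                               cards[i + 1L] - 1L)
    }
  }
  colnames(values) <- g$names
  as_discrete_dataset(values, cards)
}

#' Derive a constraint set from a known true structure
#'
#' For `kind = "edge"`, a uniformly random `floor(fraction * |E|)`-subset of
#' the true edges becomes required edge constraints. For `kind = "path"`,
#' the same count of (ancestor, descendant) pairs is drawn from the true
#' transitive closure as required path constraints. Either way the truth
#' itself satisfies the result, so the set is consistent by construction.
#'
#' @param truth a `bn_dag` (or `bayesian_network`).
#' @param fraction fraction of the true edge count to draw, in `[0, 1]`.
#' @param kind `"edge"` or `"path"`.
#' @param seed integer seed.
#' @return a [constraint_set()] of required constraints.
#' @export
sample_constraints_from_truth <- function(truth, fraction, kind = c("edge", "path"),
                                          seed = 1L) {
  if (inherits(truth, "bayesian_network")) truth <- truth$structure
  kind <- match.arg(kind)
  stopifnot(fraction >= 0, fraction <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  edges <- tidy.bn_dag(truth)
  m <- floor(fraction * nrow(edges))
  if (kind == "edge") {
    pick <- if (m > 0L) edges[sample.int(nrow(edges), m), ] else edges[0, ]
    cs <- constraint_set(edges = if (m) cbind(pick, required = TRUE) else NULL,
                         names = truth$names)
  } else {
    anc <- dag_ancestor_masks(truth)
    pairs <- do.call(rbind, lapply(seq_len(truth$n) - 1L, function(y) {
      a <- decode_subset(anc[y + 1L], truth$n)
      if (!length(a)) return(NULL)
      data.frame(from = truth$names[a + 1L], to = truth$names[y + 1L])
    }))
    m <- min(m, if (is.null(pairs)) 0L else nrow(pairs))
    pick <- if (m > 0L) pairs[sample.int(nrow(pairs), m), ] else NULL
    cs <- constraint_set(paths = if (m) cbind(pick, required = TRUE) else NULL,
                         names = truth$names)
  }
  cs
}

#' Embedded benchmark networks
#'
#' * `"asia"` — the 8-node binary chest-clinic network with its canonical
#'   conditional probability tables.
#' * `"sachs"` — the 11-node protein-signalling consensus structure
#'   (17 edges); the shipped CPTs are *synthetic* (seed-pinned Dirichlet
#'   draws over 3 states), as flagged in the fixture file name.
#' * `"constructed18"` — a seed-pinned 18-node [random_network()]
#'   stand-in for an externally constructed benchmark.
#'
#' Integer node labels used by path-constraint lists map to the fixture
#' variable order (1-based): see the fixture JSON files under
#' `inst/extdata/`.
#'
#' @param name one of `"asia"`, `"sachs"`, `"constructed18"`.
#' @return a [bayesian_network()].
#' @export
benchmark_fixture <- function(name = c("asia", "sachs", "constructed18")) {
  name <- match.arg(name)
  if (name == "constructed18") {
    return(random_network(18, edge_prob = 0.15, cardinality = 2L,
                          dirichlet_alpha = 0.5, seed = 181L))
  }
  file <- switch(name, asia = "asia.json", sachs = "sachs_synthetic.json")
  path <- system.file("extdata", file, package = "priordp")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  read_network_json(path)
}

#' The path-constraint lists used in the small-sample validity experiments
#'
#' Required ancestor pairs for the benchmark fixtures, given as integer
#' labels into the fixture variable order (1-based), e.g. Asia's seven
#' pairs 1=>6, 2=>6, 2=>8, 3=>7, 3=>8, 4=>7, 4=>8.
#'
#' @param name fixture name.
#' @return a [constraint_set()] of required path constraints.
#' @export
fixture_path_constraints <- function(name = c("asia", "sachs")) {
  name <- match.arg(name)
  pairs <- switch(name,
    asia = rbind(c(1, 6), c(2, 6), c(2, 8), c(3, 7), c(3, 8), c(4, 7), c(4, 8)),
    sachs = rbind(c(1, 2), c(1, 4), c(1, 5), c(1, 7), c(1, 8), c(2, 5),
                  c(2, 8), c(3, 4), c(4, 6), c(5, 6), c(9, 11)))
  bn <- benchmark_fixture(name)
  nms <- bn$structure$names
  constraint_set(paths = data.frame(from = nms[pairs[, 1]], to = nms[pairs[, 2]],
                                    required = TRUE),
                 names = nms)
}
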