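#' Structural Hamming distance between two DAGs
#'
#' Counts the edge insertions, deletions and reversals needed to turn `a`
#' into `b`; a reversal counts as 1 (conventions differ; this one is
#' stated because it matters when comparing reported distances).
#'
#' @param a,b `bn_dag` objects over the same variable domain.
#' @return non-negative integer.
#' @export
shd <- function(a, b) {
  stopifnot(inherits(a, "bn_dag"), inherits(b, "bn_dag"))
  if (a$n != b$n || !identical(a$names, b$names))
    stop("DAGs are over different variable domains", call. = FALSE)
  d <- 0L
  for (j in seq_len(a$n)) {
    for (i in seq_len(a$n)) {
      if (i == j) next
      in_a <- mask_has(a$parents[j], i - 1L)
      in_b <- mask_has(b$parents[j], i - 1L)
      rev_a <- mask_has(a$parents[i], j - 1L)
      if (in_a && !in_b) {
        # reversal counted once, from the perspective of the edge in `a`
        d <- d + 1L
      } else if (!in_a && in_b && !rev_a) {
        d <- d + 1L
      }
    }
  }
  d
}

#' Edge precision and recall of a learned DAG against the truth
#'
#' Directed-edge counts: precision = true edges among learned, recall =
#' learned edges among true.
#'
#' @param learned,truth `bn_dag` objects on the same domain.
#' @return list with `precision`, `recall`, `tp`, `n_learned`, `n_true`.
#' @export
edge_precision_recall <- function(learned, truth) {
  el <- tidy.bn_dag(learned); et <- tidy.bn_dag(truth)
  kl <- paste(el$from, el$to); kt <- paste(et$from, et$to)
  tp <- length(intersect(kl, kt))
  list(precision = if (length(kl)) tp / length(kl) else 1,
       recall = if (length(kt)) tp / length(kt) else 1,
       tp = tp, n_learned = length(kl), n_true = length(kt))
}

#' Verify that a DAG satisfies a constraint set
#'
#' Required edges must be present and forbidden edges absent; required
#' paths must appear in the transitive closure and forbidden paths must
#' not. All violations are returned, none thrown.
#'
#' @param g a `bn_dag`.
#' @param cs a [constraint_set()] over (a subset of) `g`'s domain.
#' @return list with `ok` (logical) and `violations` (tibble of
#'   `kind`, `from`, `to`).
#' @export
check_constraint_satisfaction <- function(g, cs) {
  stopifnot(inherits(g, "bn_dag"))
  anc <- dag_ancestor_masks(g)
  v <- list()
  nm <- function(i) cs$names[i + 1L]
  e <- cs$edges
  for (k in seq_len(nrow(e))) {
    has <- mask_has(g$parents[e$to[k] + 1L], e$from[k])
    if (has != e$required[k])
      v[[length(v) + 1L]] <- c(if (e$required[k]) "missing_edge" else "forbidden_edge",
                               nm(e$from[k]), nm(e$to[k]))
  }
  p <- cs$paths
  for (k in seq_len(nrow(p))) {
    has <- mask_has(anc[p$to[k] + 1L], p$from[k])
    if (has != p$required[k])
      v[[length(v) + 1L]] <- c(if (p$required[k]) "missing_path" else "forbidden_path",
                               nm(p$from[k]), nm(p$to[k]))
  }
  violations <- if (length(v)) {
    tibble::tibble(kind = vapply(v, `[`, character(1), 1L),
                   from = vapply(v, `[`, character(1), 2L),
                   to = vapply(v, `[`, character(1), 3L))
  } else {
    tibble::tibble(kind = character(0), from = character(0), to = character(0))
  }
  list(ok = nrow(violations) == 0L, violations = violations)
}

#' Run a truth-in / metrics-out learning experiment
#'
#' Samples data from a fixture network, derives a constraint set from the
#' true structure, learns with and without the constraints on the identical
#' score cache, and reports structural metrics plus planning-space sizes
#' for both runs. With `replicates > 1`, metrics are medians over
#' replicate seeds and the last replicate's structures are kept.
#'
#' @param fixture fixture name ([benchmark_fixture()]) or a
#'   `bayesian_network` to use as truth.
#' @param n_samples training sample size per replicate.
#' @param constraint_kind `"edge"` or `"path"`.
#' @param fraction fraction of true edges (or as many closure pairs) to
#'   turn into required constraints.
#' @param seed base integer seed; replicate `r` uses `seed + r - 1`.
#' @param replicates number of replicate draws.
#' @return a one-row tibble: `shd`, `edge_precision`, `edge_recall`,
#'   `constraints_satisfied`, `score_learned`, `score_unconstrained`,
#'   `score_truth`, `planning_space`, `planning_space_unconstrained`,
#'   plus the run parameters.
#' @export
run_experiment <- function(fixture, n_samples, constraint_kind = "edge",
                           fraction = 0.5, seed = 1L, replicates = 1L) {
  bn <- if (inherits(fixture, "bayesian_network")) fixture
        else benchmark_fixture(fixture)
  truth <- bn$structure
  one <- function(s) {
    d <- forward_sample(bn, n_samples, seed = s)
    cs <- sample_constraints_from_truth(truth, fraction, constraint_kind,
                                        seed = s)
    cache <- compute_score_cache(d)
    fit_c <- bn_learn_cache(cache, cs)
    fit_u <- bn_learn_cache(cache, empty_constraints(truth$names))
    pr <- edge_precision_recall(fit_c$dag, truth)
    sat <- check_constraint_satisfaction(fit_c$dag, cs)
    truth_score <- tryCatch(network_score(cache, truth), error = function(e) NA_real_)
    list(shd = shd(fit_c$dag, truth), precision = pr$precision,
         recall = pr$recall, satisfied = sat$ok,
         score_learned = fit_c$score, score_unconstrained = fit_u$score,
         score_truth = truth_score,
         space_c = fit_c$planning_space, space_u = fit_u$planning_space,
         fit = fit_c)
  }
  runs <- lapply(seed + seq_len(replicates) - 1L, one)
  g <- function(f) vapply(runs, `[[`, numeric(1), f)
  tibble::tibble(
    fixture = if (is.character(fixture)) fixture else "custom",
    n_samples = n_samples, constraint_kind = constraint_kind,
    fraction = fraction, replicates = replicates,
    shd = median(g("shd")),
    edge_precision = median(g("precision")),
    edge_recall = median(g("recall")),
    constraints_satisfied = all(vapply(runs, `[[`, logical(1), "satisfied")),
    score_learned = median(g("score_learned")),
    score_unconstrained = median(g("score_unconstrained")),
    score_truth = median(g("score_truth")),
    planning_space = runs[[1]]$space_c,
    planning_space_unconstrained = runs[[1]]$space_u)
}
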