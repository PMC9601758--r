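#' Learn an optimal Bayesian network structure from discrete data
#'
#' End-to-end exact structure learning: computes the BIC local-score cache
#' up to the sample-size parent bound, builds per-child sparse parent
#' graphs in the mode the constraint set requires, runs the
#' constraint-pruned dynamic program over the order graph, and returns the
#' globally optimal constrained structure.
#'
#' @param data a data frame / matrix of integer state codes, or a
#'   [as_discrete_dataset()].
#' @param constraints a [constraint_set()] over the data's variables, or
#'   `NULL` for unconstrained learning.
#' @param max_parents override for the parent bound (default
#'   [max_parents()] of the sample size).
#' @param cardinalities optional explicit per-variable state counts.
#' @return a `bn_fit`: list with `dag`, `score`, `planning_space` (admitted
#'   non-empty order-graph entries), `layer_sizes`, `nmp`, `N`, `cache`,
#'   and `constraints`. Has [tidy()][generics::tidy],
#'   [glance()][generics::glance] and `plot()` methods.
#' @examples
#' bn <- benchmark_fixture("asia")
#' d <- forward_sample(bn, 200, seed = 7)
#' fit <- bn_learn(d)
#' glance(fit)
#' @export
bn_learn <- function(data, constraints = NULL, max_parents = NULL,
                     cardinalities = NULL) {
  data <- as_discrete_dataset(data, cardinalities)
  if (is.null(constraints)) constraints <- empty_constraints(data$names)
  stopifnot(inherits(constraints, "constraint_set"))
  if (constraints$n != data$n)
    stop("constraint set and data disagree on the variable domain", call. = FALSE)
  bad <- check_consistency(constraints)
  if (nrow(bad))
    stop("inconsistent constraints: ", paste(bad$detail, collapse = "; "),
         call. = FALSE)
  cache <- compute_score_cache(data, nmp = max_parents)
  bn_learn_cache(cache, constraints)
}

#' @rdname bn_learn
#' @param cache a precomputed [compute_score_cache()] (alternative entry
#'   point when several constraint sets are compared on identical scores).
#' @export
bn_learn_cache <- function(cache, constraints) {
  spgs <- build_parent_graphs(cache, constraints)
  res <- dp_learn(spgs, constraints, cache$n, names = cache$names)
  structure(list(dag = res$dag, score = res$score,
                 planning_space = count_order_graph_entries(cache$n, constraints),
                 layer_sizes = res$layer_sizes, nmp = cache$nmp, N = cache$N,
                 cache = cache, constraints = constraints,
                 engine = res$engine),
            class = "bn_fit")
}

#' @export
print.bn_fit <- function(x, ...) {
  cat("<bn_fit> ", x$dag$n, " variables, ",
      sum(mask_size(x$dag$parents, x$dag$n)), " edges, score ",
      format(x$score), "\n", sep = "")
  cat("  N = ", x$N, ", parent bound = ", x$nmp,
      ", planning space = ", format(x$planning_space, big.mark = ","),
      " entries\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Edge list of a fitted structure
#' @param x a `bn_fit`.
#' @param ... unused.
#' @return tibble with columns `from`, `to`, `family_score`.
#' @export
tidy.bn_fit <- function(x, ...) {
  e <- tidy.bn_dag(x$dag)
  fs <- vapply(match(e$to, x$dag$names), function(i)
    cache_score(x$cache, i - 1L, x$dag$parents[i]), numeric(1))
  e$family_score <- fs
  e
}

#' One-row summary of a fitted structure
#' @param x a `bn_fit`.
#' @param ... unused.
#' @export
glance.bn_fit <- function(x, ...) {
  tibble::tibble(
    n_vars = x$dag$n,
    n_edges = sum(mask_size(x$dag$parents, x$dag$n)),
    score = x$score,
    N = x$N,
    nmp = x$nmp,
    planning_space = x$planning_space,
    n_constraints = nrow(x$constraints$edges) + nrow(x$constraints$paths))
}

#' Plot a learned structure
#'
#' Draws the DAG with `igraph` when available; falls back to printing the
#' edge list otherwise.
#'
#' @param x a `bn_fit` or `bn_dag`.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.bn_fit <- function(x, ...) plot(x$dag, ...)

#' @export
plot.bn_dag <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    print(tidy.bn_dag(x))
    return(invisible(x))
  }
  e <- tidy.bn_dag(x)
  g <- igraph::graph_from_data_frame(e, directed = TRUE,
                                     vertices = data.frame(name = x$names))
  plot(g, layout = igraph::layout_with_sugiyama(g)$layout, ...)
  invisible(x)
}

#' ggplot2 rendering of a learned structure
#'
#' Lays variables out left-to-right by topological depth and draws directed
#' edges as arrows. Requires `ggplot2`.
#'
#' @param object a `bn_fit` or `bn_dag`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bn_fit <- function(object, ...) autoplot.bn_dag(object$dag, ...)

#' @rdname autoplot.bn_fit
#' @exportS3Method ggplot2::autoplot
autoplot.bn_dag <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("autoplot needs the ggplot2 package", call. = FALSE)
  g <- object
  depth <- integer(g$n)
  for (i in topo_order(g$parents, g$n)) {
    pa <- decode_subset(g$parents[i + 1L], g$n)
    depth[i + 1L] <- if (length(pa)) max(depth[pa + 1L]) + 1L else 0L
  }
  pos <- data.frame(name = g$names, x = depth, y = stats::ave(
    seq_len(g$n), depth, FUN = function(v) seq_along(v) - (length(v) + 1) / 2))
  e <- tidy.bn_dag(g)
  seg <- merge(merge(e, pos, by.x = "from", by.y = "name"),
               pos, by.x = "to", by.y = "name",
               suffixes = c("", "end"))
  p <- ggplot2::ggplot()
  if (nrow(seg)) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = x, y = y, xend = xend, yend = yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "in"),
                             type = "closed"),
      colour = "grey40")
  }
  p + ggplot2::geom_label(data = pos,
                          ggplot2::aes(x = x, y = y, label = name)) +
    ggplot2::theme_void()
}
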