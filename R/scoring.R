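#' Parent-count bound justified by the BIC penalty
#'
#' In a BIC-optimal network no variable can have more parents than the
#' penalty term allows to pay for: the bound used here is
#' `ceiling(log2(N / log2(N)))`, floored at 1. It grows slowly with the
#' sample size `N` (3 parents at N = 20, 7 at N = 1000) and can be
#' overridden wherever it is consumed (`max_parents` arguments).
#'
#' @param N sample count, at least 2.
#' @return integer parent bound, >= 1.
#' @examples
#' max_parents(20)    # 3
#' max_parents(1000)  # 7
#' @export
max_parents <- function(N) {
  if (length(N) != 1L || is.na(N) || N < 2) stop("N must be >= 2", call. = FALSE)
  max(1L, as.integer(ceiling(log2(N / log2(N)))))
}

#' BIC local score of one (child, parent set) family
#'
#' Natural-log BIC: `sum_jk N_jk * ln(N_jk / N_j) - (ln N / 2) * q * (r - 1)`
#' where `j` runs over parent configurations, `k` over child states,
#' `N_jk` are joint counts, `N_j` parent-configuration counts, `r` the
#' child cardinality and `q` the full product of parent cardinalities
#' (unobserved configurations contribute nothing to the likelihood but are
#' still penalised). `0 * ln 0` is taken as 0. The total BIC of a network
#' is the sum of these family scores (decomposability).
#'
#' @param data a [as_discrete_dataset()] (or coercible).
#' @param child 0-based variable index of the child.
#' @param parents integer subset mask of the parents.
#' @return the family score (finite real, log scale).
#' @export
bic_local_score <- function(data, child, parents) {
  data <- as_discrete_dataset(data)
  if (mask_has(parents, child)) stop("child cannot be its own parent", call. = FALSE)
  pa <- decode_subset(parents, data$n)
  r <- data$cardinalities[child + 1L]
  q <- if (length(pa)) prod(data$cardinalities[pa + 1L]) else 1
  x <- data$values[, child + 1L]
  if (length(pa)) {
    cfg <- integer(data$N)
    for (p in pa) {  # lowest parent index most significant
      cfg <- cfg * data$cardinalities[p + 1L] + data$values[, p + 1L]
    }
  } else {
    cfg <- integer(data$N)
  }
  joint <- cfg * r + x
  njk <- tabulate(joint + 1L, nbins = q * r)
  nj <- tabulate(cfg + 1L, nbins = q)
  nz <- njk > 0L
  ll <- sum(njk[nz] * log(njk[nz] / rep(nj, each = r)[nz]))
  ll - (log(data$N) / 2) * q * (r - 1)
}

#' Precompute the local-score cache
#'
#' Scores every (child, parent set) family with `|parent set| <= nmp` and
#' child not in the parent set, for all children. The cache is the single
#' source of family scores for the sparse parent graphs, the dynamic
#' program and the exhaustive oracle, so all of them optimise the identical
#' objective.
#'
#' @param data a discrete dataset (or coercible).
#' @param nmp parent bound; defaults to [max_parents()] of the sample size.
#' @return a `score_cache`: per-child numeric vectors indexed by
#'   `parent mask + 1` (NA where no entry), plus `n`, `nmp`, `N`,
#'   `cardinalities` and `names`.
#' @export
compute_score_cache <- function(data, nmp = NULL) {
  data <- as_discrete_dataset(data)
  if (is.null(nmp)) nmp <- max_parents(data$N)
  nmp <- as.integer(nmp)
  stopifnot(nmp >= 0L)
  n <- data$n
  full <- encode_subset(seq_len(n) - 1L, n)
  scores <- vector("list", n)
  for (child in seq_len(n) - 1L) {
    ground <- bitwAnd(full, bitwNot(mask_bit(child)))
    masks <- subsets_up_to(ground, n, nmp)
    s <- rep(NA_real_, bitwShiftL(1L, n))
    for (m in masks) s[m + 1L] <- bic_local_score(data, child, m)
    scores[[child + 1L]] <- s
  }
  structure(list(scores = scores, n = n, nmp = nmp, N = data$N,
                 cardinalities = data$cardinalities, names = data$names),
            class = "score_cache")
}

#' @export
print.score_cache <- function(x, ...) {
  cat("<score_cache> ", x$n, " variables, nmp = ", x$nmp,
      ", N = ", x$N, "\n", sep = "")
  invisible(x)
}

# family-score lookup; errors on a miss (miss means the caller asked for a
# parent set outside the cached bound)
cache_score <- function(cache, child, mask) {
  s <- cache$scores[[child + 1L]][mask + 1L]
  if (is.na(s)) stop("no cached score for child ", child, " mask ", mask, call. = FALSE)
  s
}

#' Total network score from a cache
#'
#' Sum of the cached family scores of a DAG (decomposability).
#'
#' @param cache a [compute_score_cache()] result.
#' @param g a `bn_dag` over the same domain.
#' @return total score (real).
#' @export
network_score <- function(cache, g) {
  stopifnot(inherits(g, "bn_dag"), g$n == cache$n)
  sum(vapply(seq_len(g$n) - 1L,
             function(i) cache_score(cache, i, g$parents[i + 1L]), numeric(1)))
}

#' Serialise a score cache to / from a TSV file
#'
#' Implementation-internal tabular format: columns `child` (0-based index),
#' `mask` (parent subset mask) and `score`.
#'
#' @param cache a `score_cache`.
#' @param path file path.
#' @export
write_score_cache <- function(cache, path) {
  rows <- list()
  for (child in seq_len(cache$n) - 1L) {
    s <- cache$scores[[child + 1L]]
    idx <- which(!is.na(s))
    rows[[child + 1L]] <- data.frame(child = child, mask = idx - 1L,
                                     score = s[idx])
  }
  df <- do.call(rbind, rows)
  hdr <- sprintf("# n=%d nmp=%d N=%d cards=%s names=%s", cache$n, cache$nmp,
                 cache$N, paste(cache$cardinalities, collapse = ","),
                 paste(cache$names, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_cache
#' @export
read_score_cache <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[A-Za-z]+=[^ ]+", hdr))[[1]]
  meta <- setNames(sub("^[A-Za-z]+=", "", kv), sub("=.*", "", kv))
  n <- as.integer(meta[["n"]])
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  scores <- replicate(n, rep(NA_real_, bitwShiftL(1L, n)), simplify = FALSE)
  for (k in seq_len(nrow(df))) {
    scores[[df$child[k] + 1L]][df$mask[k] + 1L] <- df$score[k]
  }
  structure(list(scores = scores, n = n, nmp = as.integer(meta[["nmp"]]),
                 N = as.integer(meta[["N"]]),
                 cardinalities = as.integer(strsplit(meta[["cards"]], ",")[[1]]),
                 names = strsplit(meta[["names"]], ",")[[1]]),
            class = "score_cache")
}
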