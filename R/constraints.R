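#' Deterministic prior knowledge: edge and path constraints
#'
#' A constraint set collects required/forbidden direct edges (`X -> Y`: X is
#' a parent of Y) and required/forbidden directed paths (`X => Y`: X is an
#' ancestor of Y). Constraints are given as data frames with columns
#' `from`, `to` (variable names) and `required` (logical); either argument
#' may be `NULL` or empty.
#'
#' @param edges data frame of edge constraints (`from`, `to`, `required`).
#' @param paths data frame of path constraints (`from`, `to`, `required`).
#' @param names character vector of the full variable domain, used to map
#'   names to indices; unknown names are errors.
#' @return a `constraint_set` with 0-based index columns and the mask of all
#'   constrained variables (`var_mask`).
#' @examples
#' cs <- constraint_set(
#'   edges = data.frame(from = "X1", to = "X3", required = TRUE),
#'   paths = data.frame(from = "X4", to = "X3", required = FALSE),
#'   names = paste0("X", 1:5))
#' @export
constraint_set <- function(edges = NULL, paths = NULL, names) {
  canon <- function(df, what) {
    if (is.null(df) || nrow(df) == 0L)
      return(data.frame(from = integer(0), to = integer(0),
                        required = logical(0)))
    stopifnot(all(c("from", "to", "required") %in% colnames(df)))
    fi <- match(df$from, names); ti <- match(df$to, names)
    if (anyNA(fi) || anyNA(ti))
      stop("unknown variable name in ", what, " constraints: ",
           paste(unique(c(df$from[is.na(fi)], df$to[is.na(ti)])), collapse = ", "),
           call. = FALSE)
    if (any(fi == ti))
      stop(what, " constraint endpoints must differ", call. = FALSE)
    out <- data.frame(from = fi - 1L, to = ti - 1L,
                      required = as.logical(df$required))
    if (anyDuplicated(out)) out <- unique(out)
    out
  }
  e <- canon(edges, "edge"); p <- canon(paths, "path")
  vm <- encode_subset(unique(c(e$from, e$to, p$from, p$to)), length(names))
  structure(list(edges = e, paths = p, var_mask = vm, n = length(names),
                 names = names),
            class = "constraint_set")
}

#' An empty constraint set over a domain
#' @param names variable names of the domain.
#' @export
empty_constraints <- function(names) constraint_set(NULL, NULL, names)

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set> ", nrow(x$edges), " edge and ", nrow(x$paths),
      " path constraints over ", x$n, " variables\n", sep = "")
  invisible(x)
}

has_constraints <- function(cs) nrow(cs$edges) + nrow(cs$paths) > 0L

has_path_constraints <- function(cs) nrow(cs$paths) > 0L

# required relations (edges pooled with paths: an edge implies ancestry)
required_relations <- function(cs) {
  rbind(cs$edges[cs$edges$required, c("from", "to")],
        cs$paths[cs$paths$required, c("from", "to")])
}

#' Check a constraint set for internal consistency
#'
#' Reports, without throwing: direct contradictions (the same pair declared
#' both required and forbidden in the same relation), cycles among required
#' relations (required edges and required paths pooled, since an edge
#' implies ancestry), and a required edge whose reverse path is required.
#'
#' @param cs a [constraint_set()].
#' @return a tibble of violations (`kind`, `detail`); zero rows mean the
#'   set is consistent.
#' @export
check_consistency <- function(cs) {
  stopifnot(inherits(cs, "constraint_set"))
  viol <- list()
  nm <- function(i) cs$names[i + 1L]
  for (df in list(edge = cs$edges, path = cs$paths)) {
    key <- paste(df$from, df$to)
    both <- intersect(key[df$required], key[!df$required])
    for (b in both) {
      ij <- as.integer(strsplit(b, " ")[[1]])
      viol[[length(viol) + 1L]] <- c("contradiction",
        paste0(nm(ij[1]), " -> ", nm(ij[2]), " both required and forbidden"))
    }
  }
  req <- required_relations(cs)
  if (nrow(req)) {
    parents <- integer(cs$n)
    for (k in seq_len(nrow(req))) {
      parents[req$to[k] + 1L] <- bitwOr(parents[req$to[k] + 1L],
                                        mask_bit(req$from[k]))
    }
    if (!is_acyclic(parents)) {
      viol[[length(viol) + 1L]] <- c("cycle",
        "required edges/paths form a directed cycle")
    } else {
      # a required edge X->Y with required path Y=>X (in closure) is a cycle;
      # caught above. Direct reverse-requirement check kept for clear reports.
      er <- cs$edges[cs$edges$required, ]
      pr <- cs$paths[cs$paths$required, ]
      for (k in seq_len(nrow(er))) {
        if (any(pr$from == er$to[k] & pr$to == er$from[k]))
          viol[[length(viol) + 1L]] <- c("cycle",
            paste0("required edge ", nm(er$from[k]), " -> ", nm(er$to[k]),
                   " conflicts with required reverse path"))
      }
    }
  }
  if (length(viol)) {
    tibble::tibble(kind = vapply(viol, `[`, character(1), 1L),
                   detail = vapply(viol, `[`, character(1), 2L))
  } else {
    tibble::tibble(kind = character(0), detail = character(0))
  }
}

#' Build the constraint graph over the constrained variables
#'
#' The constraint graph has one directed edge per *required* relation
#' (required edges and required paths alike; both assert ancestry).
#' Forbidden relations contribute no edges — they act only in parent-set
#' queries. Construction fails if the required relations are cyclic, i.e.
#' the constraint set is unsatisfiable.
#'
#' @param cs a consistent [constraint_set()].
#' @return a `constraint_graph`: list with `parents` (masks over the full
#'   domain), `var_mask`, `n`.
#' @export
build_constraint_graph <- function(cs) {
  bad <- check_consistency(cs)
  if (nrow(bad))
    stop("inconsistent constraint set: ", paste(bad$detail, collapse = "; "),
         call. = FALSE)
  req <- required_relations(cs)
  parents <- integer(cs$n)
  for (k in seq_len(nrow(req))) {
    parents[req$to[k] + 1L] <- bitwOr(parents[req$to[k] + 1L],
                                      mask_bit(req$from[k]))
  }
  structure(list(parents = parents, var_mask = cs$var_mask, n = cs$n),
            class = "constraint_graph")
}

#' Roots of the constraint graph restricted to a variable subset
#'
#' Among the variables of `remaining`, returns those with no constraint-graph
#' parent inside `remaining` — the variables whose required ancestors have
#' all been placed already.
#'
#' @param gc a [build_constraint_graph()] result.
#' @param remaining subset mask (must be within the constrained variables).
#' @return subset mask of the roots.
#' @export
subgraph_roots <- function(gc, remaining) {
  out <- 0L
  for (i in decode_subset(remaining, gc$n)) {
    if (bitwAnd(gc$parents[i + 1L], remaining) == 0L)
      out <- bitwOr(out, mask_bit(i))
  }
  out
}

#' Admissible order-graph extensions of a subset
#'
#' Given a subset `u` already admitted to the order graph, the variables
#' that may be appended as the next leaf are the unconstrained variables
#' plus the roots of the constraint graph restricted to the not-yet-placed
#' constrained variables — appending anything else would strand a required
#' ancestor behind its descendant.
#'
#' @param u subset mask of the placed variables.
#' @param gc a `constraint_graph`.
#' @param n domain size.
#' @return subset mask of admissible extension variables (disjoint from `u`).
#' @export
allowed_extensions <- function(u, gc, n) {
  full <- encode_subset(seq_len(n) - 1L, n)
  free <- bitwAnd(full, bitwNot(bitwOr(u, gc$var_mask)))
  rem <- bitwAnd(gc$var_mask, bitwNot(u))
  bitwAnd(bitwOr(free, subgraph_roots(gc, rem)), bitwNot(u))
}

#' Does a subset violate the required-ancestry pruning rule?
#'
#' A subset `u` must be removed from the order graph iff some required
#' ancestry `X => Y` — inferable from the constraint set by transitive
#' closure of the required relations — has `Y` in `u` but `X` outside it:
#' any completion would place `X` after its required descendant.
#'
#' @param u subset mask.
#' @param cs a `constraint_set`.
#' @return logical scalar.
#' @export
violates_order_constraint <- function(u, cs) {
  gc <- build_constraint_graph(cs)
  anc <- dag_ancestor_masks(new_dag(gc$parents, cs$names))
  for (y in decode_subset(u, cs$n)) {
    if (bitwAnd(anc[y + 1L], bitwNot(u)) != 0L) return(TRUE)
  }
  FALSE
}

#' Read / write a constraint set as JSON
#'
#' Format: `{"edges": [{"from": "A", "to": "B", "required": true}, ...],
#' "paths": [...]}` with variables referenced by name.
#'
#' @param path file path.
#' @param names full variable domain for index mapping.
#' @return `read_constraints_json()`: a `constraint_set`.
#' @export
read_constraints_json <- function(path, names) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  constraint_set(edges = obj$edges, paths = obj$paths, names = names)
}

#' @rdname read_constraints_json
#' @param cs a `constraint_set`.
#' @export
write_constraints_json <- function(cs, path) {
  reframe <- function(df) {
    if (nrow(df) == 0L) return(list())
    data.frame(from = cs$names[df$from + 1L], to = cs$names[df$to + 1L],
               required = df$required)
  }
  jsonlite::write_json(list(edges = reframe(cs$edges), paths = reframe(cs$paths)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
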