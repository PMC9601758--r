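nms5 <- paste0("X", 1:5)

test_that("consistency checker reports contradictions and cycles", {
  cs <- constraint_set(paths = data.frame(from = c("X1", "X2"),
                                          to = c("X2", "X1"),
                                          required = TRUE),
                       names = nms5)
  v <- check_consistency(cs)
  expect_true("cycle" %in% v$kind)

  cs2 <- constraint_set(edges = data.frame(from = "X1", to = "X2",
                                           required = c(TRUE, FALSE)),
                        names = nms5)
  expect_true("contradiction" %in% check_consistency(cs2)$kind)

  # the worked constraint pair: X1 -> X3 required, X4 -> X3 forbidden
  cs3 <- constraint_set(edges = data.frame(from = c("X1", "X4"),
                                           to = c("X3", "X3"),
                                           required = c(TRUE, FALSE)),
                        names = nms5)
  expect_identical(nrow(check_consistency(cs3)), 0L)

  # required edge with required reverse path
  cs4 <- constraint_set(edges = data.frame(from = "X1", to = "X2", required = TRUE),
                        paths = data.frame(from = "X2", to = "X1", required = TRUE),
                        names = nms5)
  expect_true("cycle" %in% check_consistency(cs4)$kind)
})

test_that("unknown variable names are hard errors", {
  expect_error(constraint_set(edges = data.frame(from = "Z9", to = "X1",
                                                 required = TRUE),
                              names = nms5),
               "unknown variable")
})

test_that("constraint graph has one edge per required relation only", {
  cs <- constraint_set(edges = data.frame(from = c("X1", "X4"),
                                          to = c("X3", "X3"),
                                          required = c(TRUE, FALSE)),
                       names = nms5)
  gc <- build_constraint_graph(cs)
  expect_identical(gc$parents, c(0L, 0L, 1L, 0L, 0L))  # single edge X1 -> X3
  gc0 <- build_constraint_graph(empty_constraints(nms5))
  expect_identical(gc0$parents, rep(0L, 5))
  # chained required paths: no explicit transitive edge is added
  cs2 <- constraint_set(paths = data.frame(from = c("X1", "X2"),
                                           to = c("X2", "X3"), required = TRUE),
                        names = nms5)
  gc2 <- build_constraint_graph(cs2)
  expect_identical(gc2$parents, c(0L, 1L, 2L, 0L, 0L))
})

test_that("subgraph roots match a brute-force incoming-edge scan", {
  cs <- constraint_set(paths = data.frame(from = c("X1", "X2"),
                                          to = c("X2", "X3"), required = TRUE),
                       names = nms5)
  gc <- build_constraint_graph(cs)
  rem <- encode_subset(c(1, 2), 5)  # {X2, X3}; X1 placed -> X2 becomes root
  expect_identical(subgraph_roots(gc, rem), encode_subset(1, 5))
  expect_identical(subgraph_roots(gc, gc$var_mask), encode_subset(0, 5))
  for (s in 1:15) {
    n <- 6L
    csr <- random_constraints(n, "path", seed = s, n_required = 3, n_forbidden = 0)
    gcr <- build_constraint_graph(csr)
    rem <- bitwAnd(gcr$var_mask,
                   encode_subset(which(runif(n) < 0.6) - 1L, n))
    got <- subgraph_roots(gcr, rem)
    want <- 0L
    for (i in decode_subset(rem, n)) {
      if (bitwAnd(gcr$parents[i + 1L], rem) == 0L)
        want <- bitwOr(want, bitwShiftL(1L, i))
    }
    expect_identical(got, want)
  }
})

test_that("allowed extensions exclude required descendants until ready", {
  n <- 4L
  cs <- constraint_set(edges = data.frame(from = "X1", to = "X2", required = TRUE),
                       names = paste0("X", 1:4))
  gc <- build_constraint_graph(cs)
  expect_identical(decode_subset(allowed_extensions(0L, gc, n), n),
                   c(0L, 2L, 3L))                      # X2 excluded at the start
  expect_identical(decode_subset(allowed_extensions(1L, gc, n), n),
                   c(1L, 2L, 3L))                      # after X1, X2 is admissible
})

test_that("order-constraint violation uses the closure of required relations", {
  cs <- constraint_set(paths = data.frame(from = "X1", to = "X2", required = TRUE),
                       names = nms5)
  expect_true(violates_order_constraint(encode_subset(1, 5), cs))
  expect_false(violates_order_constraint(encode_subset(c(0, 1), 5), cs))
  chain <- constraint_set(paths = data.frame(from = c("X1", "X2"),
                                             to = c("X2", "X3"), required = TRUE),
                          names = nms5)
  expect_true(violates_order_constraint(encode_subset(2, 5), chain))  # inferred X1 => X3
})

test_that("iterating allowed extensions generates exactly the admissible subsets", {
  # soundness + completeness of the root-based expansion rule vs the
  # required-ancestry predicate, over random consistent constraint sets
  for (s in 1:25) {
    n <- sample(4:6, 1)
    kind <- if (s %% 2) "edge" else "path"
    cs <- random_constraints(n, kind, seed = s, n_required = 3, n_forbidden = 2)
    gc <- build_constraint_graph(cs)
    reached <- logical(2^n)
    reached[1] <- TRUE
    frontier <- 0L
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (x in decode_subset(allowed_extensions(u, gc, n), n)) {
          v <- bitwOr(u, bitwShiftL(1L, x))
          if (!reached[v + 1L]) { reached[v + 1L] <- TRUE; nxt <- c(nxt, v) }
        }
      }
      frontier <- nxt
    }
    admissible <- !vapply(0:(2^n - 1), violates_order_constraint,
                          logical(1), cs = cs)
    expect_identical(reached, admissible)
    # forbidden relations must not influence the expansion
    renames <- function(df) {
      if (nrow(df) == 0L) return(NULL)
      data.frame(from = cs$names[df$from + 1L], to = cs$names[df$to + 1L],
                 required = df$required)
    }
    csr <- constraint_set(
      edges = renames(cs$edges[cs$edges$required, ]),
      paths = renames(cs$paths[cs$paths$required, ]), names = cs$names)
    gcr <- build_constraint_graph(csr)
    for (u in sample(which(reached) - 1L, min(8, sum(reached)))) {
      expect_identical(allowed_extensions(u, gc, n),
                       allowed_extensions(u, gcr, n))
      expect_identical(bitwAnd(allowed_extensions(u, gc, n), u), 0L)
    }
  }
})

test_that("constraint JSON round-trips", {
  cs <- constraint_set(
    edges = data.frame(from = c("X1", "X4"), to = c("X3", "X3"),
                       required = c(TRUE, FALSE)),
    paths = data.frame(from = "X2", to = "X5", required = TRUE),
    names = nms5)
  path <- withr::local_tempfile(fileext = ".json")
  write_constraints_json(cs, path)
  cs2 <- read_constraints_json(path, nms5)
  expect_identical(cs2$edges, cs$edges)
  expect_identical(cs2$paths, cs$paths)
  expect_identical(cs2$var_mask, cs$var_mask)
})
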