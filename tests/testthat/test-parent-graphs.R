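test_that("edge-constrained bitvector query reproduces the worked table", {
  n <- 5L
  spg <- table1_spg()
  u <- encode_subset(c(0, 1, 3, 4), n)
  q <- query_best_parents_edge(spg, u,
                               required = encode_subset(c(0, 1), n),
                               forbidden = encode_subset(3, n))
  expect_identical(decode_subset(q$mask, n), c(0L, 1L, 4L))  # {X1, X2, X5}
  expect_identical(q$score, 3)
  expect_identical(q$valid, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # without constraints the top stored set wins
  q0 <- query_best_parents_edge(spg, u)
  expect_identical(decode_subset(q0$mask, n), c(0L, 4L))     # {X1, X5}
  expect_identical(q0$score, 5)
})

test_that("path-constrained query reproduces the worked table", {
  fx <- table2_fixture()
  q <- query_best_parents_path(fx$spg, fx$u, required_anc = c(0L, 1L),
                               des_masks = fx$des)
  expect_identical(decode_subset(q$mask, 5), c(2L, 3L))      # {X3, X4}
  expect_identical(q$score, 3)
  expect_identical(q$valid, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(q$cvalids[[1]], c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(q$cvalids[[2]], c(TRUE, TRUE, TRUE, FALSE, TRUE))
  q0 <- query_best_parents_path(fx$spg, fx$u)
  expect_identical(q0$score, 5)                              # {X2, X4}
})

test_that("membership bit arrays are recomputable from the stored masks", {
  spg <- table1_spg()
  for (v in seq_len(5) - 1L) {
    expect_identical(spg$membership[[v + 1L]],
                     bitwAnd(spg$masks, bitwShiftL(1L, v)) != 0L)
  }
})

test_that("unconstrained construction stores only dominating sets", {
  for (s in 1:10) {
    n <- sample(4:6, 1)
    cache <- random_score_cache(n, nmp = n - 1L, seed = s)
    for (child in seq_len(n) - 1L) {
      spg <- build_spg_unconstrained(cache, child)
      expect_true(0L %in% spg$masks)                 # empty set always stored
      expect_true(all(diff(spg$scores) <= 0))        # sorted non-increasing
      # no stored set has a stored proper subset scoring >= it
      for (i in seq_along(spg$masks)) {
        for (j in seq_along(spg$masks)) {
          if (i == j) next
          mi <- spg$masks[i]; mj <- spg$masks[j]
          if (mj != mi && bitwAnd(mj, mi) == mj) {
            expect_gt(spg$scores[i], spg$scores[j])
          }
        }
      }
      # the top stored subset of every U attains the brute-force max
      full <- encode_subset(seq_len(n) - 1L, n)
      ground <- bitwAnd(full, bitwNot(bitwShiftL(1L, child)))
      for (u in sample(0:(2^n - 1), 12)) {
        u <- bitwAnd(u, ground)
        got <- query_best_parents_edge(spg, u)
        want <- brute_best_parents(cache, child, u)
        expect_identical(got$score, want$score)
      }
    }
  }
})

test_that("single-candidate-parent table stores at most the two relevant sets", {
  cache <- random_score_cache(2, nmp = 1L, seed = 7)
  spg <- build_spg_unconstrained(cache, 0L)
  s_empty <- cache$scores[[1]][1L]
  s_one <- cache$scores[[1]][3L]   # parent set {X2}
  if (s_one > s_empty) {
    expect_setequal(spg$masks, c(0L, 2L))
  } else {
    expect_identical(spg$masks, 0L)
  }
})

test_that("edge-constrained construction excludes forbidden parents and
           answers constrained queries exactly", {
  nms <- paste0("X", 1:5)
  cs_fig <- constraint_set(edges = data.frame(from = c("X1", "X4"),
                                              to = c("X3", "X3"),
                                              required = c(TRUE, FALSE)),
                           names = nms)
  for (s in 1:10) {
    cache <- random_score_cache(5, nmp = 3L, seed = s + 40)
    spg <- build_spg_edge(cache, 2L, cs_fig)
    # no stored set contains the forbidden parent X4
    expect_true(all(!priordp:::mask_has(spg$masks, 3L)))
    req <- encode_subset(0, 5); forb <- encode_subset(3, 5)
    full_u <- encode_subset(c(0, 1, 3, 4), 5)
    for (u in c(full_u, encode_subset(c(0, 1), 5), encode_subset(c(0, 4), 5))) {
      got <- query_best_parents_edge(spg, u, required = req, forbidden = forb)
      want <- brute_best_parents(cache, 2L, u, required = req, forbidden = forb)
      expect_identical(got$score, want$score)
      expect_identical(got$mask, want$mask)
    }
  }
})

test_that("path-mode tables: tails get the full combinatorial table,
           non-tails the unconstrained one", {
  nms <- paste0("X", 1:5)
  cs <- constraint_set(paths = data.frame(from = "X1", to = "X5",
                                          required = TRUE),
                       names = nms)
  cache <- random_score_cache(5, nmp = 2L, seed = 77)
  spg_tail <- build_spg_path(cache, 4L, cs)
  expect_identical(length(spg_tail$masks), 11L)  # 1 + C(4,1) + C(4,2)
  expect_identical(spg_tail$mode, "full")
  spg_non <- build_spg_path(cache, 1L, cs)
  ref <- build_spg_unconstrained(cache, 1L)
  expect_identical(spg_non$masks, ref$masks)
  expect_identical(spg_non$scores, ref$scores)
})

test_that("path query equals a linear-scan oracle on random instances", {
  set.seed(99)
  for (s in 1:15) {
    n <- 5L
    cache <- random_score_cache(n, nmp = 3L, seed = s + 500)
    child <- sample(seq_len(n) - 1L, 1)
    nms <- paste0("X", 1:n)
    cs <- constraint_set(paths = data.frame(from = nms[1], to = nms[child + 1L],
                                            required = TRUE)[child != 0L, ],
                         names = nms)
    spg <- build_spg_path(cache, child, cs)
    g_u_masks <- random_dag_masks(n, p = 0.4, seed = s + 600)
    des <- priordp:::dag_descendant_masks_raw(g_u_masks, n)
    others <- setdiff(seq_len(n) - 1L, child)
    u <- encode_subset(others, n)
    ra <- sample(others, min(2, length(others)))
    fa <- setdiff(others, ra)[1]
    got <- tryCatch(
      query_best_parents_path(spg, u, required_anc = ra,
                              forbidden_anc = fa, des_masks = des),
      error = function(e) NULL)
    want <- brute_best_parents_spg(spg, u, ra, fa, des)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got$score, want$score)
      expect_identical(got$mask, want$mask)
    }
  }
})

test_that("constrained query score never exceeds the unconstrained score", {
  for (s in 1:10) {
    cache <- random_score_cache(5, nmp = 3L, seed = s + 900)
    spg <- build_spg_unconstrained(cache, 0L)
    u <- encode_subset(1:4, 5)
    q0 <- query_best_parents_edge(spg, u)
    q1 <- query_best_parents_edge(spg, u, required = encode_subset(1, 5))
    if (!is.null(q1)) expect_lte(q1$score, q0$score)
  }
})

test_that("an over-constrained query signals infeasibility instead of crashing", {
  spg <- table1_spg()
  # forbid every variable stored anywhere except the empty set, then
  # require one of them: nothing can survive
  q <- query_best_parents_edge(spg, u = encode_subset(c(0, 1, 3, 4), 5),
                               required = encode_subset(0, 5),
                               forbidden = encode_subset(c(1, 3, 4), 5))
  # {X1} survives that; tighten to a genuinely empty result
  q2 <- query_best_parents_edge(spg, u = encode_subset(c(1, 3, 4), 5),
                                required = encode_subset(1, 5),
                                forbidden = encode_subset(c(3, 4), 5))
  expect_identical(decode_subset(q$mask, 5), 0L)
  expect_null(q2)
})
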