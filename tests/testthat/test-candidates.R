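test_that("connected-subset enumeration matches the power-set oracle", {
  for (seed in 1:30) {
    n <- sample(4:10, 1)
    rg <- rand_graph(n, runif(1, 0.2, 0.7), seed = seed + 500)
    net <- ppin(rg$edges, vertices = rg$vertices)
    got <- enumerate_connected_subsets(net, 1, n)
    want <- brute_connected_subsets(rg$edges, ppin_vertices(net), 1, n)
    expect_setequal(vapply(got, set_key, ""), vapply(want, set_key, ""))
    expect_false(anyDuplicated(vapply(got, set_key, "")) > 0)
    # and with a size window
    got2 <- enumerate_connected_subsets(net, 2, 4)
    want2 <- brute_connected_subsets(rg$edges, ppin_vertices(net), 2, 4)
    expect_setequal(vapply(got2, set_key, ""), vapply(want2, set_key, ""))
  }
})

test_that("closed-form subset counts hold on cliques and paths", {
  # K_n: every non-empty subset is connected
  k6 <- generate_clique_fixture(6)$network
  expect_length(enumerate_connected_subsets(k6, 2, 6), 2^6 - 6 - 1)
  expect_length(enumerate_connected_subsets(k6, 2, 3), choose(6, 2) + choose(6, 3))
  # P_n: connected subsets of size >= 2 are the contiguous intervals
  pn <- ppin(data.frame(a = sprintf("p%02d", 1:7), b = sprintf("p%02d", 2:8),
                        w = 1))
  expect_length(enumerate_connected_subsets(pn, 2, 8), choose(8, 2))
  # edgeless part yields nothing at min_size 2
  iso <- ppin(data.frame(a = character(), b = character(), w = double()),
              vertices = c("a", "b", "c"))
  expect_length(enumerate_connected_subsets(iso, 2, 3), 0)
})

test_that("triangle and path enumerations match the worked examples", {
  tri <- ppin(data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"), w = 1))
  got <- enumerate_connected_subsets(tri, 2, 3)
  expect_setequal(vapply(got, set_key, ""),
                  c("a|b", "a|c", "b|c", "a|b|c"))
  pth <- ppin(data.frame(a = c("a", "b"), b = c("b", "c"), w = 1))
  got2 <- enumerate_connected_subsets(pth, 1, 3)
  expect_length(got2, 6)  # {a,c} excluded as disconnected
  expect_false("a|c" %in% vapply(got2, set_key, ""))
})

test_that("cohesion reproduces hand-evaluated values and its invariants", {
  lone <- ppin(data.frame(a = "x", b = "y", w = 0.6))
  expect_equal(cohesion(lone, c("x", "y")), 0.6)
  tri <- ppin(data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"), w = 1))
  expect_equal(cohesion(tri, c("a", "b", "c")), 2)
  pth <- ppin(data.frame(a = c("a", "b"), b = c("b", "c"), w = 1))
  expect_equal(cohesion(pth, c("a", "b", "c")), 10 / 9)
  # restriction rule: only within-set edges count
  expect_equal(cohesion(tri, c("a", "b")), 1)
  # linearity in the weights
  tri3 <- tri; tri3$weight <- tri3$weight * 2.5
  expect_equal(cohesion(tri3, c("a", "b", "c")), 5)
  # monotone in subset size within a uniform clique: (k-1) * bw closed form
  k7 <- generate_clique_fixture(7)$network
  vals <- vapply(2:7, function(k) {
    cohesion(k7, ppin_vertices(k7)[1:k])
  }, double(1))
  expect_equal(vals, (2:7) - 1)
  expect_true(all(diff(vals) > 0))
  expect_error(cohesion(tri, character()), "non-empty")
})

test_that("ranking dedups by neighbourhood affinity against more cohesive sets", {
  # identical sets: lower cohesion dies
  r <- rank_and_dedup(tibble::tibble(
    members = list(c("A", "B"), c("A", "B")), cohesion = c(5, 4)))
  expect_equal(nrow(r), 1L)
  expect_equal(r$cohesion, 5)
  # disjoint sets: both survive
  r2 <- rank_and_dedup(tibble::tibble(
    members = list(c("A", "B"), c("C", "D")), cohesion = c(5, 4)))
  expect_equal(nrow(r2), 2L)
  # NA = 4/8 = 0.5 >= 0.25: only the more cohesive {A,B,C,D} survives
  r3 <- rank_and_dedup(tibble::tibble(
    members = list(c("A", "B"), c("A", "B", "C", "D")), cohesion = c(3, 5)),
    sim_threshold = 0.25)
  expect_equal(r3$members, list(c("A", "B", "C", "D")))
  # chainwise: a set similar only to an already-deleted set still dies
  r4 <- rank_and_dedup(tibble::tibble(
    members = list(c("A", "B", "C", "D"), c("A", "B", "E"), c("B", "E", "G", "H")),
    cohesion = c(5, 4, 3)), sim_threshold = 0.25)
  # {A,B,E} dies against {A,B,C,D} (NA = 4/12); {B,E,G,H} dies against the
  # deleted {A,B,E} (NA = 4/12) although its NA to the kept set is only 1/16
  expect_equal(nrow(r4), 1L)
  expect_equal(r4$members, list(c("A", "B", "C", "D")))
  # survivors are pairwise dissimilar
  set.seed(77)
  cands <- tibble::tibble(
    members = replicate(60, sample(LETTERS[1:12], sample(2:5, 1)),
                        simplify = FALSE),
    cohesion = runif(60))
  kept <- rank_and_dedup(cands, sim_threshold = 0.3)
  if (nrow(kept) > 1) {
    for (i in seq_len(nrow(kept) - 1)) {
      for (j in (i + 1):nrow(kept)) {
        expect_lt(neighborhood_affinity(kept$members[[i]], kept$members[[j]]),
                  0.3)
      }
    }
  }
})

test_that("top-fraction selection uses a ceiling and preserves order", {
  ranked <- tibble::tibble(members = list("a", "b", "c", "d"),
                           cohesion = c(4, 3, 2, 1))
  expect_equal(nrow(select_top_fraction(ranked, 0.5)), 2L)
  expect_equal(select_top_fraction(ranked, 0.5)$cohesion, c(4, 3))
  expect_equal(nrow(select_top_fraction(ranked[1, ], 0.5)), 1L)
  expect_equal(nrow(select_top_fraction(ranked, 1)), 4L)
})

test_that("the full pipeline recovers disjoint cliques exactly and is deterministic", {
  fix <- generate_clique_fixture(c(3, 4, 5))
  res <- run_bops(fix$network, keep_fraction = 1)
  expect_equal(vapply(res$members, set_key, ""),
               vapply(rev(fix$complexes$members), set_key, ""))
  m <- evaluate_complexes(res, fix$complexes)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)

  # empty network -> empty prediction set
  empty <- ppin(data.frame(a = character(), b = character(), w = double()))
  expect_equal(nrow(run_bops(empty)), 0L)

  # byte-identical output across two runs
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_complexes(run_bops(fix$network), f1)
  write_complexes(run_bops(fix$network), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("pipeline guards its parameter contracts", {
  net <- generate_clique_fixture(3)$network
  expect_error(run_bops(net, max_size = 30, maxp = 20), "max_size")
  expect_error(run_bops(net, min_size = 1), "min_size")
  expect_error(segment_ppin(net, maxp = 0), "maxp")
})
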