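test_that("neighbourhood affinity matches its definition", {
  expect_equal(neighborhood_affinity(c("A", "B"), c("A", "B")), 1)
  expect_equal(neighborhood_affinity(c("A", "B"), c("C", "D")), 0)
  expect_equal(neighborhood_affinity(c("A", "B", "C"), c("B", "C", "D")), 4 / 9)
  expect_equal(neighborhood_affinity(c("B", "C", "D"), c("A", "B", "C")), 4 / 9)
  expect_error(neighborhood_affinity(character(), "A"), "non-empty")
})

test_that("match counts and precision/recall/F reproduce the worked example", {
  pred <- complex_set(list(c("A", "B", "C")))
  ref <- complex_set(list(c("B", "C", "D"), c("X", "Y")))
  mc <- match_counts(pred, ref, omega = 0.25)
  expect_equal(mc, list(n_cp = 1L, n_cb = 1L))
  m <- evaluate_complexes(pred, ref, omega = 0.25)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f_score, 2 / 3, tolerance = 1e-12)

  expect_equal(match_counts(complex_set(list()), ref),
               list(n_cp = 0L, n_cb = 0L))
  same <- complex_set(list(c("A", "B"), c("C", "D", "E")))
  expect_equal(match_counts(same, same), list(n_cp = 2L, n_cb = 2L))
})

test_that("Sn/PPV/ACC reproduce the worked example and fixed points", {
  spa <- sn_ppv_acc(complex_set(list(c("A", "B", "C"))),
                    complex_set(list(c("B", "C", "D"))))
  expect_equal(spa$sn, 2 / 3, tolerance = 1e-12)
  expect_equal(spa$ppv, 1)
  expect_equal(spa$acc, sqrt(2 / 3), tolerance = 1e-12)

  same <- complex_set(list(c("A", "B"), c("C", "D", "E")))
  expect_equal(sn_ppv_acc(same, same), list(sn = 1, ppv = 1, acc = 1))
  expect_equal(
    sn_ppv_acc(complex_set(list(c("A", "B"))), complex_set(list(c("X", "Y")))),
    list(sn = 0, ppv = 0, acc = 0))
})

test_that("metric outputs stay in [0,1] and ACC^2 = Sn * PPV", {
  set.seed(31)
  for (rep in 1:10) {
    pred <- complex_set(replicate(6, sample(LETTERS, sample(2:6, 1)),
                                  simplify = FALSE))
    ref <- complex_set(replicate(5, sample(LETTERS, sample(2:6, 1)),
                                 simplify = FALSE))
    m <- evaluate_complexes(pred, ref)
    vals <- unlist(m[c("precision", "recall", "f_score", "sn", "ppv", "acc",
                       "mmr")])
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(m$acc^2, m$sn * m$ppv, tolerance = 1e-12)
    expect_lte(m$mmr, m$recall + 1e-12)
  }
})

test_that("MMR reproduces the worked example and the matching oracle", {
  expect_equal(mmr(complex_set(list(c("A", "B"))),
                   complex_set(list(c("A", "B")))), 1)
  # NA({C,D},{C,E}) = 1/4: matching weight 1 + 0.25 over 2 references
  expect_equal(mmr(complex_set(list(c("A", "B"), c("C", "D"))),
                   complex_set(list(c("A", "B"), c("C", "E"))),
                   omega = 0.25), 0.625)
  # a reference split across two disjoint predictions: only one part matches
  split_pred <- complex_set(list(c("A", "B"), c("C", "D")))
  whole_ref <- complex_set(list(c("A", "B", "C", "D")))
  # each part has NA = 4/8 = 0.5 but only one is allowed to match
  expect_equal(mmr(split_pred, whole_ref), 0.5)
  # random instances against the brute-force matching oracle
  set.seed(99)
  for (rep in 1:25) {
    np <- sample(2:6, 1); nb <- sample(2:6, 1)
    pred <- complex_set(replicate(np, sample(LETTERS[1:10], sample(2:4, 1)),
                                  simplify = FALSE))
    ref <- complex_set(replicate(nb, sample(LETTERS[1:10], sample(2:4, 1)),
                                 simplify = FALSE))
    w <- outer(seq_len(np), seq_len(nb), Vectorize(function(i, j) {
      v <- neighborhood_affinity(pred$members[[i]], ref$members[[j]])
      if (v >= 0.25) v else 0
    }))
    expect_equal(mmr(pred, ref, omega = 0.25), brute_matching(w) / nb,
                 tolerance = 1e-12)
  }
})

test_that("perfect non-overlapping prediction is a fixed point of every metric", {
  cs <- complex_set(list(c("A", "B", "C"), c("D", "E"), c("F", "G", "H", "I")))
  m <- evaluate_complexes(cs, cs)
  expect_equal(unlist(m[c("precision", "recall", "f_score", "sn", "ppv",
                          "acc", "mmr")]),
               c(precision = 1, recall = 1, f_score = 1, sn = 1, ppv = 1,
                 acc = 1, mmr = 1))
})

test_that("size filtering keeps order and respects the bound", {
  cs <- complex_set(list(LETTERS[1:2], LETTERS[3:7], LETTERS[8:19]))
  expect_equal(size_filter(cs, 10)$size, c(2L, 5L))
  expect_equal(size_filter(cs, 12)$size, c(2L, 5L, 12L))
  expect_equal(nrow(size_filter(complex_set(list()), 10)), 0L)
})

test_that("regression degree and ERR reproduce the worked fixtures", {
  expect_equal(regression_degree(c("A", "B", "C", "D"), c("A", "E")), 0.25)
  expect_equal(regression_degree(c("A", "B"), c("A", "B", "C")), 1)
  expect_equal(regression_degree(c("A", "B"), c("X")), 0)

  net <- ppin(data.frame(a = c("A", "B"), b = c("B", "C"), w = 1))
  ref <- complex_set(list(c("A", "B", "C")))
  # no cuts: ERR = 1
  seg <- segment_ppin(balance_weights(net), maxp = 10)
  expect_equal(expected_regression_ratio(ref, seg, net), 1)
  # {A,B} | {C}: RD = 2/3 >= 0.25 -> still 1
  expect_equal(
    expected_regression_ratio(ref, list(c("A", "B"), "C"), net), 1)
  # 5-complex shattered into singletons: RD = 1/5 < 0.25 -> 0
  net5 <- generate_clique_fixture(5)$network
  ref5 <- complex_set(list(ppin_vertices(net5)))
  shatter <- as.list(ppin_vertices(net5))
  expect_equal(expected_regression_ratio(ref5, shatter, net5), 0)
  # references absent from the network -> explicit error
  expect_error(
    expected_regression_ratio(complex_set(list(c("Q", "R", "S", "T", "U"))),
                              shatter, net5),
    "recallable")
})

test_that("hypergeometric minimum p-value matches enumeration", {
  # |V|=10, |F|=5, |C|=2, k=2 -> 10/45
  ann <- tibble::tibble(protein = sprintf("p%02d", 1:5), group = "G1")
  res <- min_p_value(c("p01", "p02"), ann, universe_size = 10)
  expect_equal(res$p_value, 10 / 45, tolerance = 1e-12)
  expect_equal(res$group, "G1")
  expect_equal(res$k, 2L)
  # F = whole universe -> p = 1
  ann_all <- tibble::tibble(protein = sprintf("p%02d", 1:6), group = "ALL")
  expect_equal(min_p_value(c("p01", "p02"), ann_all, 6)$p_value, 1)
  expect_equal(min_p_value(sprintf("p%02d", 1:6), ann_all, 6)$p_value, 1)
  # unannotated complex
  expect_true(is.na(min_p_value(c("zz"), ann, 10)$p_value))

  # exhaustive oracle across universe/group/draw combinations
  for (nv in c(6, 9, 12)) {
    for (nf in c(2, 4, nv - 1)) {
      for (nc in c(2, 3, 5)) {
        ann2 <- tibble::tibble(protein = sprintf("u%02d", seq_len(nf)),
                               group = "G")
        for (k in 1:min(nf, nc)) {
          members <- c(sprintf("u%02d", seq_len(k)),
                       sprintf("x%02d", seq_len(nc - k)))
          got <- min_p_value(members, ann2, nv)$p_value
          expect_equal(got, brute_hyper_tail(nv, nf, nc, k),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # monotone in k
  ps <- vapply(1:4, function(k) {
    ann3 <- tibble::tibble(protein = sprintf("u%02d", 1:5), group = "G")
    members <- c(sprintf("u%02d", seq_len(k)), sprintf("x%02d", seq_len(4 - k)))
    min_p_value(members, ann3, 12)$p_value
  }, double(1))
  expect_true(all(diff(ps) < 0))
})

test_that("per-complex enrichment tables flag the strong-p bucket", {
  ann <- tibble::tibble(protein = sprintf("p%03d", 1:8), group = "G1")
  pred <- complex_set(list(sprintf("p%03d", 1:6), c("q001", "q002")))
  tab <- complex_enrichment(pred, ann, universe_size = 500)
  expect_equal(nrow(tab), 2L)
  expect_lt(tab$p_value[1], 1e-5)
  expect_true(is.na(tab$p_value[2]))
  expect_equal(attr(tab, "n_below_1e5"), 1L)
})
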