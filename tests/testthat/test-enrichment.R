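test_that("ranking is descending with deterministic tie-breaking", {
  st <- make_stats(c("A", "B", "C"), log2fc = 0, stat = c(2, -1, 3))
  expect_identical(rank_features(st, "stat")$feature_id, c("C", "A", "B"))

  tie <- make_stats(c("B", "A"), log2fc = 0, stat = c(1, 1))
  expect_identical(rank_features(tie, "stat")$feature_id, c("A", "B"))

  expect_error(rank_features(make_stats(character(0), numeric(0)), "stat"),
               "empty")
  dup <- make_stats(c("A", "A"), log2fc = c(1, 2))
  expect_error(rank_features(dup, "log2fc"), "duplicate")
})

test_that("enrichment score matches the hand-computed running sum", {
  st <- make_stats(c("A", "B", "C", "D", "E"), log2fc = 0, stat = c(5, 4, 3, 2, 1))
  ranked <- rank_features(st, "stat")

  # set at ranks {1, 3}: NR = 8, running sum peaks at 2/3
  res <- preranked_gsea(ranked, list(S = c("A", "C")), n_perm = 100, seed = 1)
  expect_equal(res$ES, 2 / 3, tolerance = 1e-12)
  expect_equal(res$leading_edge, 2L)

  # singleton top-ranked set attains the maximum ES of 1 (size filter relaxed)
  res1 <- preranked_gsea(ranked, list(S = "A"), n_perm = 100, seed = 1,
                         size_range = c(1, Inf))
  expect_equal(res1$ES, 1)

  expect_error(preranked_gsea(ranked, list(S = c("A", "C")), n_perm = 50),
               "n_perm")
  expect_warning(
    out <- preranked_gsea(ranked, list(S = c("A", "C"), tiny = "E"),
                          n_perm = 100, seed = 1),
    "skipping")
  expect_identical(out$set, "S")
})

test_that("ES is bounded and antisymmetric under ranking complementation", {
  withr::with_seed(73, {
    for (i in 1:20) {
      n <- 40
      ids <- sprintf("g%02d", 1:n)
      metric <- rnorm(n)
      st <- make_stats(ids, log2fc = 0, stat = metric)
      ranked <- rank_features(st, "stat")
      set <- list(S = sample(ids, sample(3:10, 1)))
      es <- preranked_gsea(ranked, set, n_perm = 100, seed = i)$ES
      expect_lte(abs(es), 1)
      flipped <- rank_features(make_stats(ids, log2fc = 0, stat = -metric), "stat")
      es_flip <- preranked_gsea(flipped, set, n_perm = 100, seed = i)$ES
      expect_equal(es_flip, -es, tolerance = 1e-12)
    }
  })
})

test_that("permutation p-values are reproducible and match fgsea's statistic", {
  withr::with_seed(11, {
    ids <- sprintf("g%03d", 1:60)
    st <- make_stats(ids, log2fc = 0, stat = sort(rnorm(60), decreasing = TRUE))
  })
  ranked <- rank_features(st, "stat")
  sets <- list(S1 = ids[c(2, 5, 9, 30)], S2 = ids[c(50, 55, 58)])
  r1 <- preranked_gsea(ranked, sets, n_perm = 500, seed = 42)
  r2 <- preranked_gsea(ranked, sets, n_perm = 500, seed = 42)
  expect_identical(r1, r2)

  skip_if_not_installed("fgsea")
  # independent cross-check of the running-sum statistic
  stats_vec <- setNames(ranked$metric, ranked$feature_id)
  for (nm in names(sets)) {
    es_fgsea <- fgsea::calcGseaStat(stats_vec,
                                    selectedStats = match(sets[[nm]],
                                                          names(stats_vec)),
                                    gseaParam = 1)
    expect_equal(r1$ES[r1$set == nm], es_fgsea, tolerance = 1e-12)
  }
})

test_that("Fisher-mode GSEA matches hypergeometric tails and validates", {
  universe <- sprintf("u%03d", 1:40)
  selected <- universe[1:20]
  sets <- list(half = universe[1:20],     # selected == set
               none = universe[21:40],    # disjoint from selected
               mix = universe[11:30])
  res <- fisher_gsea(selected, universe, sets)
  expect_equal(res$p[res$set == "none"], 1)
  # selected == set == half the universe: minimum achievable p at those margins
  expect_equal(res$p[res$set == "half"],
               brute_fisher_greater(20, 0, 0, 20), tolerance = 1e-13)
  expect_equal(res$p[res$set == "mix"],
               brute_fisher_greater(10, 10, 10, 10), tolerance = 1e-13)
  expect_true(all(res$fdr >= res$p - 1e-15))

  expect_error(fisher_gsea(c("u001", "zzz"), universe, sets), "zzz")

  # agrees with the motif module's machinery on an identical table
  ct <- contingency_enrichment(c(rep(TRUE, 10), rep(FALSE, 10)),
                               c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_equal(fisher_exact_p(10, 10, 10, 10), ct$p, tolerance = 1e-15)
})

test_that("the DDR-scale configuration matches independent tail enumeration", {
  # 31 hypo-proteins, 8 in a 134-member annotated subset of a 4087-protein
  # universe: table (8, 23, 126, 3930)
  p <- fisher_exact_p(8, 23, 126, 3930, alternative = "greater")
  expect_equal(p, brute_fisher_greater(8, 23, 126, 3930), tolerance = 1e-12)
  universe <- sprintf("p%04d", 1:4087)
  res <- fisher_gsea(universe[1:31], universe,
                     list(ddr = universe[c(1:8, 32:157)]))
  expect_equal(res$p, p, tolerance = 1e-14)
  expect_equal(res$overlap, 8L)
})
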