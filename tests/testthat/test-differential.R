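test_that("total-signal normalisation equalises column sums", {
  m <- matrix(c(2, 8, 6, 24), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  norm <- normalize_total(m)  # sums 10 and 30 -> both 20
  expect_equal(unname(colSums(norm)), c(20, 20))

  already <- matrix(c(5, 5, 4, 6), 2, 2)
  expect_equal(normalize_total(already), already)

  zero <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(NULL, c("s1", "s2")))
  expect_error(normalize_total(zero), "s2")
})

test_that("BH adjustment matches the step-up definition and validates", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
  expect_error(bh_adjust(c(0.5, 1.2)), "p-values")

  # agrees with an independent brute-force step-up on random vectors
  withr::with_seed(99, {
    for (i in 1:1000) {
      p <- runif(sample(1:50, 1))
      expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("differential test recovers noise-free effects and nulls", {
  # identical groups: log2fc 0, p 1 everywhere
  m <- matrix(5, 4, 6, dimnames = list(paste0("f", 1:4), NULL))
  de <- fit_differential(m, rep(c("c", "t"), each = 3), "log_intensity",
                         treated = "t")
  expect_equal(de$log2fc, rep(0, 4))
  expect_equal(de$p, rep(1, 4))

  # noise-free planted shift of exactly 2 on the log scale
  m2 <- cbind(matrix(10, 3, 3), matrix(12, 3, 3))
  rownames(m2) <- paste0("f", 1:3)
  de2 <- fit_differential(m2, rep(c("c", "t"), each = 3), "log_intensity",
                          treated = "t")
  expect_equal(de2$log2fc, rep(2, 3))
  expect_equal(de2$p, rep(1, 3))  # zero within-group variance => p = 1
  expect_true(all(sign(de2$stat) == sign(de2$log2fc)))

  expect_error(
    fit_differential(m2, c("c", "c", "c", "c", "c", "t"), "log_intensity"),
    ">= 2 samples")
})

test_that("differential p-values are calibrated on a synthetic null", {
  cfg <- sim_config(n_features = 2000, n_responders = 0, replicates = 3,
                    seed = 7)
  sim <- gen_rnaseq_counts(cfg)
  expect_true(all(sim$truth$class == "null"))
  expect_true(all(sim$truth$true_log2fc == 0))
  de <- fit_differential(sim$counts, rep(c("ctrl", "trt"), each = 3),
                         "counts", treated = "trt")
  frac <- mean(de$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  expect_gt(stats::ks.test(de$p, "punif")$p.value, 0.01)
})

test_that("hyperbolic threshold classifies per the boundary formula", {
  gene <- hyperbolic_threshold("genes")
  expect_equal(gene$padj_th, 0.01)
  expect_equal(gene$log2fc_th, 1.5)
  expect_equal(gene$c, 0.5)

  # |log2fc| = 2.5 under the gene preset: boundary is exactly 2.25
  expect_equal(hyperbolic_boundary(2.5, gene), 2.25)
  st <- make_stats(c("a", "b"), log2fc = c(2.5, 2.5), padj = c(1e-3, 8e-3))
  lab <- classify_hyperbolic(st, gene)$label
  expect_identical(lab, c("up", "ns"))

  # |log2fc| at the asymptote is never significant
  st2 <- make_stats("a", log2fc = 1.5, padj = 1e-300)
  expect_identical(classify_hyperbolic(st2, gene)$label, "ns")

  # phospho preset, negative fold change
  ph <- hyperbolic_threshold("phospho")
  expect_equal(hyperbolic_boundary(-0.5, ph), -log10(0.05) + 0.5 / 0.4)
  st3 <- make_stats(c("a", "b"), log2fc = c(-0.5, -0.5), padj = c(1e-3, 5e-3))
  expect_identical(classify_hyperbolic(st3, ph)$label, c("down", "ns"))

  expect_error(hyperbolic_threshold(padj_th = 0.5, log2fc_th = -1), "log2fc_th")
})

test_that("hyperbolic rule dominates the rectangular rule and converges", {
  th <- hyperbolic_threshold("genes")
  withr::with_seed(31, {
    st <- make_stats(sprintf("f%03d", 1:300),
                     log2fc = runif(300, -4, 4),
                     padj = 10^runif(300, -6, 0))
    labelled <- classify_hyperbolic(st, th)
    hyper_sig <- labelled$label != "ns"
    rect_sig <- abs(st$log2fc) > th$log2fc_th & st$padj < th$padj_th
    expect_true(all(!hyper_sig | rect_sig))  # hyperbolic set within rectangular set
  })
  # boundary converges to padj_th as |log2fc| grows (measured on the
  # adjusted-p scale, where the residual c/|log2fc| term is negligible)
  expect_lt(abs(10^(-hyperbolic_boundary(50, th)) - th$padj_th), 1e-3)
})

test_that("row z-scoring centres, scales and flags constant rows", {
  m <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(unname(zscore_rows(m)), matrix(c(-1, 0, 1), 1, 3))

  m2 <- rbind(a = c(1, 2, 3), b = c(7, 7, 7))
  expect_warning(z <- zscore_rows(m2), "constant")
  expect_equal(unname(z["b", ]), c(0, 0, 0))

  withr::with_seed(5, m3 <- matrix(rnorm(50), 5, 10))
  expect_true(all(abs(rowMeans(zscore_rows(m3))) < 1e-12))
  expect_equal(unname(apply(zscore_rows(m3), 1, sd)), rep(1, 5))
})
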