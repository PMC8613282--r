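test_that("sim_config validates its fields and names the offender", {
  expect_error(sim_config(n_responders = 50, n_features = 10), "n_responders")
  expect_error(sim_config(replicates = 1), "replicates")
  expect_error(sim_config(n_features = 0), "n_features")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  cfg <- sim_config(seed = 3)
  expect_s3_class(cfg, "sim_config")
})

test_that("every generator is bitwise-deterministic under a fixed seed", {
  cfg <- sim_config(n_features = 100, n_responders = 10, replicates = 3,
                    seed = 5)
  expect_identical(gen_rnaseq_counts(cfg), gen_rnaseq_counts(cfg))
  expect_identical(gen_phospho_dataset(cfg), gen_phospho_dataset(cfg))
  expect_identical(gen_gene_sets(5, 10, 2, sprintf("g%d", 1:50),
                                 truth = data.frame(feature_id = sprintf("g%d", 1:50),
                                                    class = rep(c("up", "null"), 25)),
                                 seed = 4),
                   gen_gene_sets(5, 10, 2, sprintf("g%d", 1:50),
                                 truth = data.frame(feature_id = sprintf("g%d", 1:50),
                                                    class = rep(c("up", "null"), 25)),
                                 seed = 4))
  p4 <- list(bottom = 0, top = 1, ic50 = 50, hill = 2)
  expect_identical(gen_dose_response(p4, noise_sd = 0.05, seed = 2),
                   gen_dose_response(p4, noise_sd = 0.05, seed = 2))
  grp <- list(a = list(n = 3, v0 = 100, rate = 0.1, noise_sd = 0.1))
  expect_identical(gen_tumor_growth(grp, seed = 6), gen_tumor_growth(grp, seed = 6))
  expect_identical(gen_interaction_edges(20, 0.2, seed = 8),
                   gen_interaction_edges(20, 0.2, seed = 8))
})

test_that("planted truth is internally consistent and recoverable", {
  cfg <- sim_config(n_features = 300, n_responders = 40, replicates = 3,
                    seed = 9)
  sim <- gen_rnaseq_counts(cfg)
  tr <- sim$truth
  expect_equal(nrow(tr), 300)
  expect_false(anyDuplicated(tr$feature_id) > 0)
  expect_identical(tr$class != "null", abs(tr$true_log2fc) > 0)
  expect_equal(sum(tr$class != "null"), 40)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_equal(dim(sim$counts), c(300, 6))

  # zero responders: all-null truth
  sim0 <- gen_rnaseq_counts(sim_config(n_features = 50, n_responders = 0,
                                       replicates = 2, seed = 1))
  expect_true(all(sim0$truth$class == "null"))
  expect_true(all(sim0$truth$true_log2fc == 0))
})

test_that("count generator recovers planted effects as dispersion vanishes", {
  cfg <- sim_config(n_features = 60, n_responders = 60, replicates = 4,
                    effect_min = 2, effect_rate = Inf, dispersion = 0,
                    depth = 5e4, seed = 13)
  sim <- gen_rnaseq_counts(cfg)
  obs <- log2(rowMeans(sim$counts[, 5:8]) / rowMeans(sim$counts[, 1:4]))
  expect_true(all(abs(obs - sim$truth$true_log2fc) < 0.05))
})

test_that("phospho generator plants exact effects, classes and S/TQ fractions", {
  # zero noise: sample log2 ratio equals the planted effect exactly
  cfg <- sim_config(n_features = 20, n_responders = 2, replicates = 3,
                    effect_min = 1.5, effect_rate = Inf, noise_sd = 0,
                    seed = 21)
  ph <- gen_phospho_dataset(cfg)
  lr <- log2(rowMeans(ph$intensity[, 4:6]) / rowMeans(ph$intensity[, 1:3]))
  expect_equal(unname(lr), ph$truth$true_log2fc, tolerance = 1e-12)
  hypo <- ph$truth$class == "down"
  expect_equal(sum(hypo), 1L)
  expect_equal(unname(lr[hypo]), -1.5)
  expect_identical(ph$sites$class[hypo], "hypo")

  # extreme motif proportions are hit exactly
  cfg2 <- sim_config(n_features = 20, n_responders = 10, replicates = 2,
                     seed = 22)
  ph2 <- gen_phospho_dataset(cfg2, stq_frac_responders = 1, stq_frac_null = 0)
  responder <- ph2$truth$class != "null"
  expect_equal(sum(ph2$sites$is_stq), 10L)
  expect_true(all(ph2$sites$is_stq[responder]))
  expect_true(all(nchar(ph2$sites$window) == 11))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY-]+$", ph2$sites$window)))
  expect_identical(substr(ph2$sites$window, 6, 6), ph2$sites$residue)
})

test_that("gene-set generator respects sizes and plants enrichment", {
  universe <- sprintf("g%03d", 1:100)
  truth <- data.frame(feature_id = universe,
                      class = c(rep("up", 20), rep("null", 80)))
  gs <- gen_gene_sets(6, c(10, 15, 20), 2, universe, truth = truth, seed = 3)
  expect_length(gs$sets, 6)
  expect_equal(unname(lengths(gs$sets)), c(10, 15, 20, 10, 15, 20))
  expect_identical(gs$enriched, c("SET_001", "SET_002"))
  # enriched sets are biased toward up-responders
  up_frac <- vapply(gs$sets, function(s) mean(s %in% universe[1:20]), numeric(1))
  expect_true(all(up_frac[1:2] >= 0.7))

  expect_error(gen_gene_sets(2, 10, 3, universe, truth = truth), "n_enriched")
  expect_error(gen_gene_sets(2, 200, 0, universe), "universe")

  # bias 0: exchangeable uniform draws, no truth needed
  gs0 <- gen_gene_sets(4, 10, 0, universe, bias = 0, seed = 1)
  expect_length(gs0$enriched, 0)
})

test_that("dose-response generator hits the midpoint and stays monotone", {
  p4 <- list(bottom = 0.1, top = 0.9, ic50 = 150, hill = 1.8)
  dr <- gen_dose_response(p4, doses = 150)
  expect_equal(dr$response, 0.5)  # (top + bottom) / 2 at the IC50

  dr8 <- gen_dose_response(p4)
  expect_equal(nrow(dr8), 8L)
  expect_true(all(diff(dr8$response) < 0))  # strictly monotone for hill > 0

  combo <- gen_dose_response(p4, ratio = 1.5)
  expect_equal(combo$dose2, 1.5 * combo$dose)

  expect_error(gen_dose_response(p4, doses = c(-5, 10)), "positive")
  expect_error(gen_dose_response(list(bottom = 1, top = 0, ic50 = 1, hill = 1)),
               "bottom")
})

test_that("tumour growth generator produces flat, growing and regressing arms", {
  flat <- gen_tumor_growth(list(g = list(n = 2, v0 = 120, rate = 0)), days = 10,
                           seed = 1)
  expect_true(all(flat$volume_mm3 == 120))

  grps <- list(control = list(n = 4, v0 = 150, rate = 0.12),
               treated = list(n = 4, v0 = 150, rate = 0),
               regress = list(n = 4, v0 = 150, rate = -2))
  gr <- gen_tumor_growth(grps, days = 14, seed = 2)
  mean_vol <- function(g, d) mean(gr$volume_mm3[gr$group == g & gr$day == d])
  expect_equal(tgi(mean_vol("treated", 0), mean_vol("treated", 14),
                   mean_vol("control", 0), mean_vol("control", 14)), 100)
  expect_equal(tgi(mean_vol("regress", 0), mean_vol("regress", 14),
                   mean_vol("control", 0), mean_vol("control", 14)), 200,
               tolerance = 1e-6)
})

test_that("interaction edge generator yields simple scored graphs", {
  full <- gen_interaction_edges(4, edge_density = 1, seed = 1)
  expect_equal(nrow(full), 6L)  # complete graph on 4 nodes
  key <- paste(pmin(full$protein_a, full$protein_b),
               pmax(full$protein_a, full$protein_b))
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(full$protein_a != full$protein_b))
  expect_true(all(full$combined_score >= 0 & full$combined_score <= 1))

  # constant sub-threshold scores: high-confidence filter empties the graph
  half <- gen_interaction_edges(6, edge_density = 1,
                                score_dist = function(n) rep(0.5, n), seed = 1)
  expect_equal(nrow(filter_high_confidence(half)), 0L)
})
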