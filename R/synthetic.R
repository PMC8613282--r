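# Synthetic-data generators with planted ground truth. Each generator
# emulates one input type of the analysis — negative-binomial RNA-seq
# counts, log-normal TMT-style phosphosite intensities with sequence
# windows, gene sets with planted enrichment, 4PL dose-response viability,
# exponential tumour growth, and scored interaction edge lists — so the
# full pipeline runs and can be validated against known effects at desk
# scale. All randomness is governed by a single seed per call; identical
# configuration and seed reproduce bitwise-identical output.

#' Simulation configuration
#'
#' Shared configuration for the expression-type generators. Effect sizes of
#' planted responders are drawn as `sign * (effect_min + Exp(effect_rate))`,
#' half up and half down.
#'
#' @param n_features number of features (genes or phosphosites).
#' @param n_responders number of features with a planted non-zero effect
#'   (`<= n_features`).
#' @param replicates replicates per condition (>= 2).
#' @param effect_min minimum absolute planted log2 fold change (default 1).
#' @param effect_rate rate of the exponential tail above `effect_min`
#'   (default 1).
#' @param dispersion negative-binomial dispersion for counts (default 0.05;
#'   0 means Poisson).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale for
#'   intensities (default 0.25).
#' @param depth mean sequencing depth per feature (counts) or median linear
#'   intensity scale (default 500).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_features = 2000L, n_responders = 100L,
                       replicates = 3L, effect_min = 1, effect_rate = 1,
                       dispersion = 0.05, noise_sd = 0.25, depth = 500,
                       seed = 1L) {
  n_features <- .assert_count(n_features, "n_features", min = 1L)
  n_responders <- .assert_count(n_responders, "n_responders", min = 0L)
  if (n_responders > n_features) {
    .fail("config", "'n_responders' (%d) exceeds 'n_features' (%d)",
          n_responders, n_features)
  }
  replicates <- .assert_count(replicates, "replicates", min = 2L)
  structure(list(
    n_features = n_features, n_responders = n_responders,
    replicates = replicates,
    effect_min = .assert_number(effect_min, "effect_min", lower = 0),
    effect_rate = .assert_number(effect_rate, "effect_rate", lower = 0),
    dispersion = .assert_number(dispersion, "dispersion", lower = 0),
    noise_sd = .assert_number(noise_sd, "noise_sd", lower = 0),
    depth = .assert_number(depth, "depth", lower = 1e-8),
    seed = .assert_count(seed, "seed")
  ), class = "sim_config")
}

# sample() without the length-1 surprise (sample(5L, 1) samples 1:5)
.sample_from <- function(x, k) x[sample.int(length(x), k)]

# planted truth table shared by the expression generators
.planted_truth <- function(prefix, config) {
  n <- config$n_features
  k <- config$n_responders
  id <- sprintf("%s%05d", prefix, seq_len(n))
  lfc <- numeric(n)
  cls <- rep("null", n)
  if (k > 0L) {
    idx <- sample.int(n, k)
    magnitude <- config$effect_min +
      stats::rexp(k, rate = max(config$effect_rate, 1e-8))
    sgn <- rep_len(c(1, -1), k)
    lfc[idx] <- sgn * magnitude
    cls[idx] <- ifelse(sgn > 0, "up", "down")
  }
  data.frame(feature_id = id, class = cls, true_log2fc = lfc,
             stringsAsFactors = FALSE)
}

#' Simulate RNA-seq counts with planted fold changes
#'
#' Draws a `n_features x (2 * replicates)` integer count matrix from a
#' negative-binomial model (dispersion 0 falls back to Poisson). Per-feature
#' base means are log-normal around `depth`; treated-condition means are
#' shifted by `2^true_log2fc` for planted responders.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (integer matrix, columns `ctrl_*`/`trt_*`)
#'   and `truth` (data.frame `feature_id`, `class`, `true_log2fc`).
#' @export
gen_rnaseq_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    truth <- .planted_truth("gene", config)
    n <- config$n_features; r <- config$replicates
    base <- config$depth * 2^rnorm(n, 0, 1)
    mu <- cbind(matrix(base, n, r), matrix(base * 2^truth$true_log2fc, n, r))
    counts <- if (config$dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
             n, 2L * r)
    } else {
      matrix(rpois(length(mu), lambda = mu), n, 2L * r)
    }
    dimnames(counts) <- list(truth$feature_id,
                             c(paste0("ctrl_", seq_len(r)),
                               paste0("trt_", seq_len(r))))
    list(counts = counts, truth = truth)
  })
}

# random 11-residue window with the given centre residue and a controlled
# +1 residue (Q or non-Q)
.random_windows <- function(n, centre, plus1_q) {
  aa <- strsplit("ACDEFGHIKLMNPRSTVWY", "")[[1L]]  # Q excluded from filler
  aa_q <- c(aa, "Q")
  flank_left <- matrix(sample(aa_q, n * 5L, replace = TRUE), n, 5L)
  flank_right <- matrix(sample(aa_q, n * 4L, replace = TRUE), n, 4L)
  plus1 <- ifelse(plus1_q, "Q", sample(aa, n, replace = TRUE))
  paste0(apply(flank_left, 1L, paste, collapse = ""), centre, plus1,
         apply(flank_right, 1L, paste, collapse = ""))
}

#' Simulate a TMT-style phosphosite dataset
#'
#' Generates linear-scale intensities that are Gaussian on the log2 scale
#' (`noise_sd`), with treated columns shifted by the planted log2 fold
#' change, plus an 11-residue sequence window per site. Responder sites
#' carry a Q at position +1 with probability `stq_frac_responders`; null
#' sites with probability `stq_frac_null`. Centre residues are S/T/Y in
#' roughly the proportions seen in phosphoproteomics (88/11.5/0.5%).
#'
#' @param config a [sim_config()] (`dispersion` unused here).
#' @param stq_frac_responders,stq_frac_null probability of an S/TQ motif
#'   among responder / null sites, each in \[0, 1\].
#' @return list with `intensity` (linear-scale matrix), `sites` (data.frame
#'   `protein_id`, `position`, `residue`, `window`, `class`, `is_stq`) and
#'   `truth`. Site `class` is `"hypo"` / `"hyper"` / `"non_dp"` from the
#'   planted truth.
#' @export
gen_phospho_dataset <- function(config, stq_frac_responders = 0.17,
                                stq_frac_null = 0.033) {
  stopifnot(inherits(config, "sim_config"))
  .assert_number(stq_frac_responders, "stq_frac_responders", 0, 1)
  .assert_number(stq_frac_null, "stq_frac_null", 0, 1)
  withr::with_seed(config$seed, {
    truth <- .planted_truth("site", config)
    n <- config$n_features; r <- config$replicates
    base_log2 <- log2(config$depth) + rnorm(n, 0, 1)
    shift <- cbind(matrix(0, n, r),
                   matrix(truth$true_log2fc, n, r))
    log2_int <- base_log2 + shift +
      matrix(rnorm(n * 2L * r, 0, config$noise_sd), n, 2L * r)
    intensity <- 2^log2_int
    dimnames(intensity) <- list(truth$feature_id,
                                c(paste0("ctrl_", seq_len(r)),
                                  paste0("trt_", seq_len(r))))
    responder <- truth$class != "null"
    stq <- logical(n)
    # extreme proportions stay exact: deterministic counts, random placement
    k_resp <- round(stq_frac_responders * sum(responder))
    k_null <- round(stq_frac_null * sum(!responder))
    stq[.sample_from(which(responder), k_resp)] <- TRUE
    stq[.sample_from(which(!responder), k_null)] <- TRUE
    centre <- sample(c("S", "T", "Y"), n, replace = TRUE,
                     prob = c(0.88, 0.115, 0.005))
    centre[stq] <- sample(c("S", "T"), sum(stq), replace = TRUE,
                          prob = c(0.88, 0.12))
    windows <- .random_windows(n, centre, stq)
    sites <- data.frame(
      protein_id = truth$feature_id, position = 6L, residue = centre,
      window = windows,
      class = c(null = "non_dp", up = "hyper", down = "hypo")[truth$class],
      stringsAsFactors = FALSE)
    sites$is_stq <- classify_stq(sites$window)
    rownames(sites) <- NULL
    list(intensity = intensity, sites = sites, truth = truth)
  })
}

#' Simulate gene-set collections with planted enrichment
#'
#' Enriched sets draw a fraction `bias` of their members from the planted
#' up-responders in `truth` (falling back to uniform draws if responders run
#' short); the remaining sets are uniform draws from the universe.
#'
#' @param n_sets number of sets.
#' @param set_sizes integer vector of set sizes (recycled to `n_sets`),
#'   each `<=` universe size.
#' @param n_enriched number of enriched sets (`<= n_sets`).
#' @param universe character vector of feature ids.
#' @param truth planted-truth data.frame (`feature_id`, `class`); required
#'   when `n_enriched > 0`.
#' @param bias fraction of an enriched set drawn from up-responders
#'   (default 0.8; 0 gives exchangeable uniform sets).
#' @param seed integer seed.
#' @return list with `sets` (named list) and `enriched` (character vector
#'   of enriched set names).
#' @export
gen_gene_sets <- function(n_sets, set_sizes, n_enriched, universe,
                          truth = NULL, bias = 0.8, seed = 1L) {
  n_sets <- .assert_count(n_sets, "n_sets", min = 1L)
  n_enriched <- .assert_count(n_enriched, "n_enriched", min = 0L)
  if (n_enriched > n_sets) {
    .fail("config", "'n_enriched' (%d) exceeds 'n_sets' (%d)", n_enriched, n_sets)
  }
  set_sizes <- rep_len(as.integer(set_sizes), n_sets)
  if (any(set_sizes > length(universe))) {
    .fail("config", "set sizes must not exceed the universe size (%d)", length(universe))
  }
  .assert_number(bias, "bias", 0, 1)
  withr::with_seed(seed, {
    up <- if (!is.null(truth)) {
      intersect(truth$feature_id[truth$class == "up"], universe)
    } else {
      character(0)
    }
    if (n_enriched > 0L && bias > 0 && length(up) == 0L) {
      .fail("config", "enriched sets requested but truth has no up-responders")
    }
    sets <- vector("list", n_sets)
    names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
    for (i in seq_len(n_sets)) {
      size <- set_sizes[i]
      if (i <= n_enriched && bias > 0) {
        k_up <- min(round(bias * size), length(up))
        members <- .sample_from(up, k_up)
        members <- c(members, .sample_from(setdiff(universe, members), size - k_up))
      } else {
        members <- .sample_from(universe, size)
      }
      sets[[i]] <- members
    }
    list(sets = sets, enriched = names(sets)[seq_len(n_enriched)])
  })
}

#' Simulate a 4PL dose-response table
#'
#' `response = 4PL(dose) + N(0, noise_sd)`. Supports fixed-ratio
#' combinations via `ratio`: the stated `doses` are agent-1 doses and a
#' second dose column `dose2 = ratio * dose` is added (the 4PL is evaluated
#' on the agent-1 dose; combination effects are modelled downstream).
#'
#' @param params list with `bottom`, `top`, `ic50`, `hill`
#'   (`bottom < top`).
#' @param doses concentrations in nM (default the 8-point grid
#'   25-1000 nM).
#' @param noise_sd Gaussian noise SD (default 0).
#' @param seed integer seed.
#' @param ratio optional fixed dose ratio for a second agent.
#' @return data.frame with columns `dose` (and `dose2` if `ratio` given)
#'   and `response`.
#' @export
gen_dose_response <- function(params,
                              doses = c(25, 50, 100, 150, 200, 300, 500, 1000),
                              noise_sd = 0, seed = 1L, ratio = NULL) {
  if (any(doses <= 0)) .fail("config", "'doses' must be positive")
  if (params$bottom >= params$top) .fail("config", "'bottom' must be below 'top'")
  withr::with_seed(seed, {
    resp <- predict_4pl(params, doses) + rnorm(length(doses), 0, noise_sd)
    out <- data.frame(dose = doses, response = resp)
    if (!is.null(ratio)) {
      out$dose2 <- ratio * doses
      out <- out[, c("dose", "dose2", "response")]
    }
    out
  })
}

#' Simulate per-animal tumour volume trajectories
#'
#' Exponential growth per animal: `V(t) = V0 * exp(rate * t) * noise`,
#' with multiplicative log-normal noise. Negative rates model regression.
#'
#' @param groups named list of group configs, each a list with `n`
#'   (animals), `v0` (initial volume, mm^3, > 0), `rate` (per-day growth
#'   rate), and optional `noise_sd` (log-scale SD, default 0).
#' @param days number of days (measurements at day 0..days, step 2).
#' @param seed integer seed.
#' @return data.frame with columns `animal`, `group`, `day`, `volume_mm3`.
#' @export
gen_tumor_growth <- function(groups, days = 14L, seed = 1L) {
  days <- .assert_count(days, "days", min = 0L)
  withr::with_seed(seed, {
    day_grid <- seq(0L, days, by = 2L)
    rows <- list()
    for (gname in names(groups)) {
      g <- groups[[gname]]
      if (g$v0 <= 0) .fail("config", "initial volume must be > 0 in group '%s'", gname)
      nsd <- g$noise_sd %||% 0
      for (i in seq_len(g$n)) {
        noise <- exp(rnorm(length(day_grid), 0, nsd))
        rows[[length(rows) + 1L]] <- data.frame(
          animal = sprintf("%s_%02d", gname, i), group = gname,
          day = day_grid,
          volume_mm3 = g$v0 * exp(g$rate * day_grid) * noise,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a scored interaction edge list
#'
#' Undirected edges without self-loops or duplicate pairs, sampled at the
#' requested density from all protein pairs, with combined scores drawn
#' from `score_dist` (default uniform on \[0, 1\]).
#'
#' @param n_proteins number of proteins (ids `PROT_1..`).
#' @param edge_density fraction of all unordered pairs to include, in
#'   (0, 1].
#' @param score_dist function `n -> n scores in [0, 1]` (default
#'   `runif`).
#' @param seed integer seed.
#' @return data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score`.
#' @export
gen_interaction_edges <- function(n_proteins, edge_density = 0.05,
                                  score_dist = stats::runif, seed = 1L) {
  n_proteins <- .assert_count(n_proteins, "n_proteins", min = 2L)
  .assert_number(edge_density, "edge_density", lower = 1e-12, upper = 1)
  withr::with_seed(seed, {
    pairs <- utils::combn(sprintf("PROT_%d", seq_len(n_proteins)), 2L)
    n_pairs <- ncol(pairs)
    k <- max(1L, round(edge_density * n_pairs))
    pick <- if (k >= n_pairs) seq_len(n_pairs) else sort(sample.int(n_pairs, k))
    scores <- score_dist(length(pick))
    if (any(scores < 0 | scores > 1)) .fail("config", "scores must be in [0, 1]")
    data.frame(protein_a = pairs[1L, pick], protein_b = pairs[2L, pick],
               combined_score = scores, stringsAsFactors = FALSE)
  })
}
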