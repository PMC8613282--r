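# Gene-set enrichment: preranked weighted Kolmogorov-Smirnov running-sum
# enrichment scores with a gene-label permutation null, and unranked
# Fisher-based over-representation with BH FDR control.

#' Rank features for preranked enrichment
#'
#' Orders features by a signed metric, descending; ties broken by feature id
#' (lexicographic) so the ranking is deterministic.
#'
#' @param stats `feature_stats` data.frame (from [fit_differential()]).
#' @param metric `"stat"` (signed test statistic) or `"log2fc"`.
#' @return data.frame with columns `feature_id`, `metric`, ordered
#'   descending; class `ranked_list`.
#' @export
rank_features <- function(stats, metric = c("stat", "log2fc")) {
  metric <- match.arg(metric)
  if (nrow(stats) == 0L) .fail("rank_features", "empty statistics table")
  if (anyDuplicated(stats$feature_id)) {
    .fail("rank_features", "duplicate feature id: %s",
          stats$feature_id[duplicated(stats$feature_id)][1L])
  }
  m <- stats[[metric]]
  if (any(!is.finite(m))) .fail("rank_features", "ranking metric must be finite")
  ord <- order(-m, stats$feature_id)
  structure(data.frame(feature_id = stats$feature_id[ord], metric = m[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# Weighted KS running-sum enrichment score (weight exponent 1):
# hits increment by |metric| / NR, misses decrement by 1 / (N - m);
# ES is the extremum of the running sum. `hits` is a logical vector
# aligned with the (descending) metric vector.
.gsea_es <- function(metric, hits) {
  n <- length(metric)
  m <- sum(hits)
  nr <- sum(abs(metric[hits]))
  inc <- numeric(n)
  if (nr > 0) {
    inc[hits] <- abs(metric[hits]) / nr
  } else {
    inc[hits] <- 1 / m  # all-zero metrics: unweighted steps
  }
  inc[!hits] <- -1 / (n - m)
  running <- cumsum(inc)
  i_max <- which.max(running); i_min <- which.min(running)
  if (running[i_max] >= -running[i_min]) running[i_max] else running[i_min]
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment scores (weight
#' exponent 1) with an empirical gene-label permutation null. P-values are
#' sign-stratified: an observed ES is compared only against permuted scores
#' of the same sign, with add-one smoothing, so extreme p-values saturate at
#' `1 / (n_same_sign + 1)` and are reported as bounds. NES divides ES by the
#' mean absolute permuted ES of matching sign. FDR is BH across all analysed
#' sets. Sets with fewer than 2 members in the ranking (or outside
#' `size_range`) are skipped with a warning.
#'
#' @param ranked a [rank_features()] result (or data.frame with
#'   `feature_id`, `metric`).
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param n_perm number of gene-label permutations (>= 100; default 10000).
#' @param seed integer seed for the permutation stream.
#' @param size_range numeric length-2; sets whose membership in the ranking
#'   falls outside this range are skipped (default `c(2, Inf)`).
#' @return data.frame with columns `set`, `ES`, `NES`, `p`, `fdr`,
#'   `n_members`, `leading_edge`.
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 10000L, seed = 1L,
                           size_range = c(2, Inf)) {
  if (n_perm < 100L) .fail("preranked_gsea", "n_perm must be >= 100 for null resolution")
  metric <- ranked$metric
  ids <- ranked$feature_id
  n <- length(ids)
  sizes <- vapply(sets, function(s) sum(ids %in% s), integer(1))
  keep <- sizes >= max(1, size_range[1L]) & sizes <= size_range[2L]
  if (any(!keep)) {
    warning(sprintf("preranked_gsea: skipping %d set(s) outside size range",
                    sum(!keep)), call. = FALSE)
  }
  sets <- sets[keep]; sizes <- sizes[keep]
  if (length(sets) == 0L) {
    return(data.frame(set = character(0), ES = numeric(0), NES = numeric(0),
                      p = numeric(0), fdr = numeric(0), n_members = integer(0),
                      leading_edge = integer(0), stringsAsFactors = FALSE))
  }

  res <- withr::with_seed(seed, {
    lapply(names(sets), function(nm) {
      hits <- ids %in% sets[[nm]]
      es <- .gsea_es(metric, hits)
      k <- sum(hits)
      perm_es <- vapply(seq_len(n_perm), function(i) {
        ph <- logical(n)
        ph[sample.int(n, k)] <- TRUE
        .gsea_es(metric, ph)
      }, numeric(1))
      same <- if (es >= 0) perm_es[perm_es >= 0] else perm_es[perm_es < 0]
      p <- (sum(abs(same) >= abs(es)) + 1) / (length(same) + 1)
      denom <- mean(abs(same))
      nes <- if (length(same) > 0 && denom > 0) es / denom else NA_real_
      # leading edge: hits at or before the running-sum extremum
      inc <- numeric(n)
      nr <- sum(abs(metric[hits]))
      inc[hits] <- if (nr > 0) abs(metric[hits]) / nr else 1 / k
      inc[!hits] <- -1 / (n - k)
      running <- cumsum(inc)
      peak <- if (es >= 0) which.max(running) else which.min(running)
      le <- if (es >= 0) sum(hits[seq_len(peak)]) else sum(hits[peak:n])
      data.frame(set = nm, ES = es, NES = nes, p = p, n_members = k,
                 leading_edge = le, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  out[, c("set", "ES", "NES", "p", "fdr", "n_members", "leading_edge")]
}

#' Fisher-based (unranked) gene-set enrichment
#'
#' One-sided over-representation test: for each set, the 2x2 table
#' (selected-in-set, selected-not-in-set, set-not-selected, rest of
#' universe) is tested with Fisher's exact test (greater), followed by BH
#' FDR correction across sets. Sets are intersected with the universe.
#'
#' @param selected character vector of selected feature ids (must be a
#'   subset of `universe`).
#' @param universe character vector of all quantified feature ids.
#' @param sets named list of character vectors.
#' @param size_range sets whose intersection with the universe falls outside
#'   this range are skipped (default `c(1, Inf)`).
#' @return data.frame with columns `set`, `overlap`, `n_selected`,
#'   `n_set`, `n_universe`, `odds_ratio`, `p`, `fdr`.
#' @export
fisher_gsea <- function(selected, universe, sets, size_range = c(1, Inf)) {
  selected <- unique(selected); universe <- unique(universe)
  missing <- setdiff(selected, universe)
  if (length(missing) > 0L) {
    .fail("fisher_gsea", "selected features outside universe: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  sets <- lapply(sets, intersect, universe)
  sizes <- lengths(sets)
  sets <- sets[sizes >= size_range[1L] & sizes <= size_range[2L]]
  n_sel <- length(selected); n_uni <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    a <- length(intersect(selected, s))
    b <- n_sel - a
    c <- length(s) - a
    d <- n_uni - n_sel - c
    odds <- if (b * c == 0) { if (a * d > 0) Inf else 0 } else (a * d) / (b * c)
    data.frame(set = nm, overlap = a, n_selected = n_sel, n_set = length(s),
               n_universe = n_uni, odds_ratio = odds,
               p = fisher_exact_p(a, b, c, d, alternative = "greater"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(0), overlap = integer(0),
                      n_selected = integer(0), n_set = integer(0),
                      n_universe = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), fdr = numeric(0)))
  }
  out$fdr <- bh_adjust(out$p)
  out
}
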