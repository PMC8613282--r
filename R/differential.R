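# Differential expression / phosphorylation: total-amount normalisation,
# a transparent per-feature two-sample test, Benjamini-Hochberg correction,
# and classification against a hyperbolic significance surface in
# (log2 fold change, adjusted p) space.

#' Normalise sample columns on total signal
#'
#' Rescales each sample column of a linear-scale intensity matrix so that all
#' column sums equal the mean of the original column sums — the total-peptide
#' -amount normalisation used for TMT reporter intensities.
#'
#' @param m numeric matrix, linear-scale intensities, samples in columns.
#' @return rescaled matrix of the same shape.
#' @export
normalize_total <- function(m) {
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    .fail("normalize_total", "sample '%s' has zero total signal",
          colnames(m)[zero][1L] %||% which(zero)[1L])
  }
  sweep(m, 2L, mean(cs) / cs, `*`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. Thin validating wrapper around
#' [stats::p.adjust()] so every stage shares one multiple-testing entry point.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    .fail("bh_adjust", "p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Per-feature differential test
#'
#' Tests each feature for a difference between treated and control samples.
#' Counts are transformed to log2 counts-per-million with a pseudocount of
#' 0.5 and then, like log intensities, tested with a per-feature Welch
#' (unequal-variance) two-sample t-test. The log2 fold change is the
#' treated-minus-control mean on the log2 scale; p-values are adjusted with
#' [bh_adjust()]. Features with zero variance in both groups get p = 1.
#'
#' @param m numeric matrix (features x samples). For `value_kind = "counts"`,
#'   raw counts; for `"log_intensity"`, values already on log2 scale.
#' @param condition character/factor of length `ncol(m)` with exactly two
#'   levels; `treated` names the treated level.
#' @param value_kind `"counts"` or `"log_intensity"`.
#' @param treated the condition level considered treated (default the
#'   second level, or `"treated"` if present).
#' @return data.frame (class `feature_stats`) with columns `feature_id`,
#'   `log2fc`, `stat`, `p`, `padj`, `label` (all `"ns"` until
#'   [classify_hyperbolic()] is applied).
#' @export
fit_differential <- function(m, condition,
                             value_kind = c("counts", "log_intensity"),
                             treated = NULL) {
  value_kind <- match.arg(value_kind)
  condition <- as.character(condition)
  if (length(condition) != ncol(m)) {
    .fail("fit_differential", "condition labels (%d) != samples (%d)",
          length(condition), ncol(m))
  }
  levs <- unique(condition)
  if (length(levs) != 2L) .fail("fit_differential", "need exactly 2 conditions, got %d", length(levs))
  if (is.null(treated)) treated <- if ("treated" %in% levs) "treated" else levs[2L]
  if (!treated %in% levs) .fail("fit_differential", "treated level '%s' not in labels", treated)
  control <- setdiff(levs, treated)
  n1 <- sum(condition == treated); n0 <- sum(condition == control)
  if (n1 < 2L || n0 < 2L) {
    .fail("fit_differential", "each condition needs >= 2 samples (have %d treated, %d control)", n1, n0)
  }

  x <- if (value_kind == "counts") {
    # median-of-ratios size factors (robust to asymmetric strong effects,
    # which bias plain total-count scaling), then log2 with pseudocount
    logg <- rowMeans(log(m))
    ok <- is.finite(logg)
    sf <- if (any(ok)) {
      apply(m[ok, , drop = FALSE], 2L, function(col) {
        exp(stats::median(log(col) - logg[ok]))
      })
    } else {
      cs <- colSums(m)
      cs / mean(cs)
    }
    log2(sweep(m, 2L, sf, `/`) + 0.5)
  } else {
    m
  }

  xt <- x[, condition == treated, drop = FALSE]
  xc <- x[, condition == control, drop = FALSE]
  mt <- rowMeans(xt); mc <- rowMeans(xc)
  vt <- apply(xt, 1L, var); vc <- apply(xc, 1L, var)
  lfc <- mt - mc

  se2 <- vt / n1 + vc / n0
  # zero variance in both groups: p = 1 (keeps BH well-defined); the statistic
  # keeps the sign of the fold change
  tstat <- ifelse(se2 > 0, lfc / sqrt(se2), ifelse(lfc == 0, 0, sign(lfc) * Inf))
  # Welch-Satterthwaite degrees of freedom
  df <- ifelse(se2 > 0,
               se2^2 / (vt^2 / (n1^2 * (n1 - 1)) + vc^2 / (n0^2 * (n0 - 1))),
               1)
  p <- ifelse(se2 > 0, 2 * pt(-abs(tstat), df), 1)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  data.frame(feature_id = rownames(m) %||% as.character(seq_len(nrow(m))),
             log2fc = lfc, stat = tstat, p = p, padj = bh_adjust(p),
             label = "ns", stringsAsFactors = FALSE) |>
    structure(class = c("feature_stats", "data.frame"))
}

#' Hyperbolic significance threshold
#'
#' Parameters of the continuous volcano-plot significance boundary: a feature
#' is significant when `|log2fc| > log2fc_th` and
#' `-log10(padj) >= -log10(padj_th) + c / sqrt(log2fc^2 - log2fc_th^2)`.
#' The required significance grows without bound as `|log2fc|` approaches the
#' fold-change cutoff and relaxes to `padj_th` for large fold changes, so the
#' hyperbolic rule is uniformly at least as stringent as the rectangular
#' cutoff pair.
#'
#' Presets match the study conventions: `"genes"` uses
#' (padj_th = 0.01, log2fc_th = 1.5, c = 0.5); `"phospho"` (also appropriate
#' for total proteome data) uses (padj_th = 0.05, log2fc_th = 0.3, c = 0.5).
#'
#' @param preset `"genes"`, `"phospho"`, or `NULL` to give explicit values.
#' @param padj_th adjusted-p threshold in (0, 1).
#' @param log2fc_th fold-change threshold, > 0.
#' @param c curve parameter, > 0.
#' @return list of class `hyperbolic_threshold`.
#' @export
hyperbolic_threshold <- function(preset = NULL, padj_th = NULL, log2fc_th = NULL,
                                 c = 0.5) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("genes", "phospho"))
    padj_th <- if (preset == "genes") 0.01 else 0.05
    log2fc_th <- if (preset == "genes") 1.5 else 0.3
    c <- 0.5
  }
  padj_th <- .assert_number(padj_th, "padj_th")
  log2fc_th <- .assert_number(log2fc_th, "log2fc_th")
  c <- .assert_number(c, "c")
  if (padj_th <= 0 || padj_th >= 1) .fail("threshold", "padj_th must be in (0, 1)")
  if (log2fc_th <= 0) .fail("threshold", "log2fc_th must be > 0")
  if (c <= 0) .fail("threshold", "c must be > 0")
  structure(list(padj_th = padj_th, log2fc_th = log2fc_th, c = c),
            class = "hyperbolic_threshold")
}

#' Hyperbolic boundary on the -log10(padj) scale
#'
#' The minimum `-log10(padj)` required for significance at a given absolute
#' log2 fold change. `Inf` at or below the fold-change threshold.
#'
#' @param log2fc numeric vector of (absolute or signed) log2 fold changes.
#' @param th a [hyperbolic_threshold()].
#' @return numeric vector of boundary values.
#' @export
hyperbolic_boundary <- function(log2fc, th) {
  stopifnot(inherits(th, "hyperbolic_threshold"))
  a <- abs(log2fc)
  out <- rep(Inf, length(a))
  in_range <- a > th$log2fc_th
  out[in_range] <- -log10(th$padj_th) +
    th$c / sqrt(a[in_range]^2 - th$log2fc_th^2)
  out
}

#' Classify features with the hyperbolic threshold
#'
#' Labels each feature `"up"`, `"down"` or `"ns"`: significant iff
#' `|log2fc|` strictly exceeds the fold-change threshold and `-log10(padj)`
#' is at or above the hyperbolic boundary; direction follows the sign of
#' `log2fc`.
#'
#' @param stats a `feature_stats` data.frame from [fit_differential()].
#' @param th a [hyperbolic_threshold()].
#' @return `stats` with the `label` column filled in.
#' @export
classify_hyperbolic <- function(stats, th) {
  stopifnot(inherits(th, "hyperbolic_threshold"))
  if (any(!is.finite(stats$log2fc)) || any(!is.finite(stats$padj))) {
    .fail("classify_hyperbolic", "log2fc and padj must be finite")
  }
  bound <- hyperbolic_boundary(stats$log2fc, th)
  sig <- -log10(stats$padj) >= bound  # Inf boundary => FALSE
  stats$label <- ifelse(sig & stats$log2fc > 0, "up",
                        ifelse(sig & stats$log2fc < 0, "down", "ns"))
  stats
}

#' Row-wise z-score normalisation
#'
#' Centres each feature row to mean 0 and scales to sample standard
#' deviation 1, as used for heatmap display of phosphorylation signals.
#' Constant rows map to all zeros with a warning.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  if (ncol(m) < 2L) .fail("zscore_rows", "need >= 2 samples")
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  const <- s == 0
  if (any(const)) {
    warning(sprintf("zscore_rows: %d constant row(s) set to zero", sum(const)),
            call. = FALSE)
    s[const] <- 1
  }
  (m - mu) / s
}
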