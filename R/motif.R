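# Phosphosite sequence windows and S/TQ (PIKK substrate) motif enrichment.
# A site is represented by its protein, 1-based position, central residue and
# an 11-character window covering positions -5..+5, padded with '-' at protein
# termini. Enrichment between response classes uses Fisher's exact test with
# the p-value computed by direct hypergeometric enumeration.

WINDOW_PAD <- "-"

#' Extract the +/-5 residue window around a phosphosite
#'
#' Returns the 11-character sequence context centred on `position`, with
#' positions beyond either protein terminus filled with `'-'`.
#'
#' @param sequence protein sequence (single string, uppercase amino acids).
#' @param position 1-based residue index within `sequence`.
#' @param flank number of residues on each side (default 5).
#' @return character scalar of length `2 * flank + 1`.
#' @export
extract_window <- function(sequence, position, flank = 5L) {
  n <- nchar(sequence)
  if (position < 1L || position > n) {
    .fail("extract_window", "position %d outside sequence of length %d", position, n)
  }
  idx <- (position - flank):(position + flank)
  chars <- rep(WINDOW_PAD, length(idx))
  ok <- idx >= 1L & idx <= n
  chars[ok] <- strsplit(substr(sequence, max(1L, position - flank),
                               min(n, position + flank)), "")[[1L]]
  paste(chars, collapse = "")
}

#' Build a phosphosite table from sequences
#'
#' Looks each site up in `sequences`, extracts its window and classifies the
#' S/TQ motif. Sites on proteins absent from the sequence set are dropped
#' with a logged count rather than an error.
#'
#' @param sites data.frame with columns `protein_id`, `position` and
#'   optionally `class` (`"hypo"`, `"hyper"`, `"non_dp"`).
#' @param sequences named character vector, as from [read_fasta()].
#' @return data.frame with columns `protein_id`, `position`, `residue`,
#'   `window`, `class`, `is_stq`.
#' @export
build_phosphosites <- function(sites, sequences) {
  known <- sites$protein_id %in% names(sequences)
  if (any(!known)) {
    .log("build_phosphosites: dropping %d site(s) on proteins absent from FASTA",
         sum(!known))
    sites <- sites[known, , drop = FALSE]
  }
  windows <- mapply(function(p, pos) extract_window(sequences[[p]], pos),
                    sites$protein_id, sites$position, USE.NAMES = FALSE)
  out <- data.frame(protein_id = sites$protein_id,
                    position = sites$position,
                    residue = substr(windows, 6L, 6L),
                    window = windows,
                    class = if ("class" %in% names(sites)) sites$class else "non_dp",
                    stringsAsFactors = FALSE)
  out$is_stq <- classify_stq(out$window)
  out
}

#' Classify the S/TQ (PIKK substrate) motif
#'
#' TRUE iff the central residue is S or T and the residue at position +1 is
#' Q — the canonical ATM/ATR substrate signature. Tyrosine sites are never
#' S/TQ. Operates on 11-character windows (centre at index 6).
#'
#' @param window character vector of 11-character site windows.
#' @return logical vector.
#' @export
classify_stq <- function(window) {
  if (any(nchar(window) != 11L)) .fail("classify_stq", "windows must be 11 characters")
  substr(window, 6L, 6L) %in% c("S", "T") & substr(window, 7L, 7L) == "Q"
}

#' Two-sided Fisher exact p by hypergeometric enumeration
#'
#' Classical two-sided Fisher p-value for the 2x2 table
#' \code{rbind(c(a, b), c(c, d))}: the sum, over the hypergeometric support
#' with the observed margins, of all table probabilities not exceeding the
#' probability of the observed table (with a small relative tolerance for
#' floating-point ties).
#'
#' @param a,b,c,d non-negative integer cell counts (foreground motif+/-,
#'   background motif+/-).
#' @param alternative `"two.sided"` (default), `"greater"` for
#'   overrepresentation of `a`, or `"less"`.
#' @return p-value in (0, 1].
#' @export
fisher_exact_p <- function(a, b, c, d, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (any(c(a, b, c, d) < 0)) .fail("fisher_exact_p", "counts must be non-negative")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (alternative == "greater") return(phyper(a - 1, r1, r2, c1, lower.tail = FALSE))
  if (alternative == "less") return(phyper(a, r1, r2, c1))
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Motif contingency enrichment between response classes
#'
#' Builds the 2x2 table counting a predicate (by default the S/TQ motif)
#' among foreground sites versus background sites and computes the odds
#' ratio, the ratio of motif proportions and a two-sided Fisher exact p.
#'
#' @param foreground,background disjoint data.frames of sites (as from
#'   [build_phosphosites()]), or logical vectors of predicate values.
#' @param predicate function mapping a site data.frame to a logical vector
#'   (default: its `is_stq` column). Ignored when logical vectors are given.
#' @return list of class `motif_contingency` with fields `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `proportion_ratio`, `p`.
#' @export
contingency_enrichment <- function(foreground, background,
                                   predicate = function(s) s$is_stq) {
  fg <- if (is.logical(foreground)) foreground else predicate(foreground)
  bg <- if (is.logical(background)) background else predicate(background)
  if (length(fg) == 0L || length(bg) == 0L) {
    .fail("contingency_enrichment", "foreground and background must be non-empty")
  }
  a <- sum(fg); b <- sum(!fg); c <- sum(bg); d <- sum(!bg)
  odds <- if (b * c == 0) {
    if (a * d > 0) Inf else 0
  } else {
    (a * d) / (b * c)
  }
  if (a == 0) odds <- 0
  prop <- if ((a + b) > 0 && (c + d) > 0 && c > 0) {
    (a / (a + b)) / (c / (c + d))
  } else if (a == 0) 0 else Inf
  structure(list(a = a, b = b, c = c, d = d,
                 odds_ratio = odds, proportion_ratio = prop,
                 p = fisher_exact_p(a, b, c, d)),
            class = "motif_contingency")
}

#' Position-specific residue enrichment
#'
#' For each flanking position (-5..-1, +1..+5; the phosphosite itself is
#' excluded) and each of the 20 amino acids, tests overrepresentation in the
#' foreground windows against the background windows with a one-sided Fisher
#' exact test, reports the log2 frequency ratio, and applies BH correction
#' across the whole position-by-residue grid. Pad characters are excluded
#' from the counts.
#'
#' @param foreground,background character vectors of 11-character windows
#'   (or site data.frames with a `window` column).
#' @return data.frame with columns `position` (-5..+5 excluding 0),
#'   `residue`, `fg_count`, `fg_total`, `bg_count`, `bg_total`, `log2_ratio`,
#'   `p`, `padj`.
#' @export
position_enrichment <- function(foreground, background) {
  fg <- if (is.data.frame(foreground)) foreground$window else foreground
  bg <- if (is.data.frame(background)) background$window else background
  if (length(fg) == 0L || length(bg) == 0L) {
    .fail("position_enrichment", "foreground and background must be non-empty")
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  positions <- setdiff(-5:5, 0L)
  rows <- list()
  for (pos in positions) {
    col <- pos + 6L
    fg_res <- substr(fg, col, col)
    bg_res <- substr(bg, col, col)
    fg_res <- fg_res[fg_res != WINDOW_PAD]
    bg_res <- bg_res[bg_res != WINDOW_PAD]
    nf <- length(fg_res); nb <- length(bg_res)
    for (r in aa) {
      a <- sum(fg_res == r); c <- sum(bg_res == r)
      fr_f <- if (nf > 0) a / nf else 0
      fr_b <- if (nb > 0) c / nb else 0
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, residue = r,
        fg_count = a, fg_total = nf, bg_count = c, bg_total = nb,
        log2_ratio = log2((fr_f + 1e-9) / (fr_b + 1e-9)),
        p = fisher_exact_p(a, nf - a, c, nb - c, alternative = "greater"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out
}
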