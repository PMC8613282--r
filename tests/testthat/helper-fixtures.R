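# Shared fixture builders. Everything is generated in code; no stored data.

# minimal feature_stats table for threshold / ranking tests
make_stats <- function(ids, log2fc, padj = rep(0.5, length(ids)),
                       stat = log2fc, p = padj) {
  structure(data.frame(feature_id = ids, log2fc = log2fc, stat = stat,
                       p = p, padj = padj, label = rep("ns", length(ids)),
                       stringsAsFactors = FALSE),
            class = c("feature_stats", "data.frame"))
}

# independent brute-force two-sided Fisher p via direct lchoose enumeration
# (kept free of dhyper/phyper so it can serve as an oracle for them)
brute_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p <- exp(lp)
  pobs <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1))
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# independent brute-force one-sided (overrepresentation) Fisher p
brute_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- a:min(r1, c1)
  sum(exp(lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(r1 + r2, c1)))
}

# independent step-up BH implementation straight from the definition
brute_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# tiny TSV matrix file on disk
write_tmp_matrix <- function(m, id_col = "feature_id") {
  path <- tempfile(fileext = ".tsv")
  write_matrix(m, path, id_col = id_col)
  path
}
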