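# Readers and writers for the plain-text formats the pipeline touches:
# TSV feature matrices, GMT gene sets, FASTA protein sequences and
# STRING-style interaction edge lists. All readers validate and reject
# malformed input rather than silently coercing it.

#' Read a feature-by-sample matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers. Duplicate feature or sample ids are an error, as are
#' non-integer values when `value_kind = "counts"`.
#'
#' @param path TSV file path.
#' @param value_kind `"counts"` (non-negative integers) or `"intensity"`
#'   (positive reals, linear scale) or `"log_intensity"`.
#' @return numeric matrix with feature ids as rownames and sample ids as
#'   colnames; `value_kind` attached as attribute `"value_kind"`.
#' @export
read_matrix <- function(path, value_kind = c("counts", "intensity", "log_intensity")) {
  value_kind <- match.arg(value_kind)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) .fail("read_matrix", "need a feature id column plus >= 1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    .fail("read_matrix", "duplicate feature id: %s", ids[duplicated(ids)][1L])
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    .fail("read_matrix", "duplicate sample id: %s", samples[duplicated(samples)][1L])
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) .fail("read_matrix", "non-numeric values in matrix body")
  if (value_kind == "counts") {
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      .fail("read_matrix", "non-integer count %s at feature '%s', sample '%s'",
            format(m[bad[1L, , drop = FALSE]]), ids[bad[1L, 1L]], samples[bad[1L, 2L]])
    }
  }
  rownames(m) <- ids
  attr(m, "value_kind") <- value_kind
  m
}

#' Write a feature matrix as TSV
#'
#' Inverse of [read_matrix()]; a write/read round trip reproduces the matrix.
#'
#' @param m numeric matrix with rownames (feature ids) and colnames (samples).
#' @param path output path.
#' @param id_col name for the feature id column (default `"feature_id"`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write_tsv(df, path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, fields `name`, `description`, then members,
#' tab-separated. Duplicate members within a set are collapsed with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors of member ids; per-set descriptions
#'   in attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      .fail("read_gmt", "line %d has %d field(s); GMT needs name, description and >= 1 member",
            i, length(f))
    }
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("read_gmt: duplicate members in set '%s' collapsed", f[1L]),
              call. = FALSE)
      members <- unique(members)
    }
    sets[[f[1L]]] <- members
    desc[f[1L]] <- f[2L]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' The id is the header token before the first whitespace; sequences are
#' uppercased. Duplicate ids and empty sequences are errors.
#'
#' @param path FASTA file path.
#' @return named character vector, id -> sequence.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    .fail("read_fasta", "duplicate sequence id: %s", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(aa))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    .fail("read_fasta", "empty sequence for id: %s", ids[empty][1L])
  }
  setNames(seqs, ids)
}

#' Read a STRING-style interaction edge list
#'
#' Whitespace- or tab-separated columns `protein_a`, `protein_b`,
#' `combined_score`. The score dialect is declared, never auto-detected:
#' `"thousand"` for the STRING download convention (integers 0-1000, divided
#' by 1000) and `"unit"` for scores already in \[0, 1\]. Duplicate unordered
#' pairs are collapsed keeping the maximum score; self-loops are an error.
#'
#' @param path edge file path. A header line is detected (non-numeric third
#'   field) and skipped.
#' @param score_scale `"unit"` or `"thousand"`.
#' @return data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score` (unit scale).
#' @export
read_edges <- function(path, score_scale = c("unit", "thousand")) {
  score_scale <- match.arg(score_scale)
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("protein_a", "protein_b", "combined_score"),
                   colClasses = c("character", "character", "character"))
  if (nrow(df) > 0L && is.na(suppressWarnings(as.numeric(df$combined_score[1L])))) {
    df <- df[-1L, , drop = FALSE]  # header line
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score)) .fail("read_edges", "non-numeric combined_score in row %d", which(is.na(score))[1L])
  if (score_scale == "thousand") {
    if (any(score < 0 | score > 1000 | score != round(score))) {
      .fail("read_edges", "score outside integer range 0-1000 under 'thousand' scale")
    }
    score <- score / 1000
  } else if (any(score < 0 | score > 1)) {
    .fail("read_edges", "score outside [0, 1] under 'unit' scale")
  }
  if (any(df$protein_a == df$protein_b)) .fail("read_edges", "self-loop edge not allowed")
  edges <- data.frame(protein_a = df$protein_a, protein_b = df$protein_b,
                      combined_score = score, stringsAsFactors = FALSE)
  dedup_edges(edges)
}

# collapse duplicate unordered pairs, keeping the maximum score
dedup_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  key <- ifelse(edges$protein_a < edges$protein_b,
                paste(edges$protein_a, edges$protein_b),
                paste(edges$protein_b, edges$protein_a))
  ord <- order(key, -edges$combined_score)
  edges <- edges[ord, , drop = FALSE]
  edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}
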