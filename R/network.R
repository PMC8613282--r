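# Protein-protein interaction subnetworks: keep only high-confidence edges
# and extract the induced first-degree neighbourhood around seed proteins
# (those carrying hypophosphorylated sites), annotated with fold changes.

#' Filter edges to high confidence
#'
#' Keeps edges whose combined score is strictly greater than `min_score`
#' (the STRING high-confidence convention, score > 0.7). Order-preserving.
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score` on the unit scale.
#' @param min_score confidence cutoff (default 0.7).
#' @return filtered data.frame.
#' @export
filter_high_confidence <- function(edges, min_score = 0.7) {
  if (any(edges$combined_score < 0 | edges$combined_score > 1)) {
    .fail("filter_high_confidence", "scores must be in [0, 1]")
  }
  out <- edges[edges$combined_score > min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' First-degree subnetwork around seed proteins
#'
#' Extracts the subgraph induced on the seeds plus all of their direct
#' neighbours: the node set is seeds and first-degree interactors, and every
#' (pre-filtered) edge with both endpoints in that set is retained —
#' including edges among non-seed neighbours. Node annotations (`log2fc`,
#' `has_stq_site`) are joined by exact protein id; unmatched nodes carry
#' `NA` fold change.
#'
#' @param edges high-confidence edge data.frame (see
#'   [filter_high_confidence()]).
#' @param seeds character vector of seed protein ids (non-empty).
#' @param annotations optional data.frame with columns `protein_id` and any
#'   of `log2fc`, `has_stq_site`.
#' @return list of class `subnetwork` with `nodes` (data.frame: `protein`,
#'   `is_seed`, `log2fc`, `has_stq_site`) and `edges` (the induced edges).
#'   If no seed appears in the edge list, the subnetwork contains the
#'   isolated seeds only and a warning is issued.
#' @export
first_degree_subnetwork <- function(edges, seeds, annotations = NULL) {
  if (length(seeds) == 0L) .fail("first_degree_subnetwork", "seed set is empty")
  seeds <- unique(seeds)
  g <- igraph::graph_from_data_frame(edges[, c("protein_a", "protein_b")],
                                     directed = FALSE)
  present <- intersect(seeds, igraph::V(g)$name)
  if (length(present) == 0L) {
    warning("first_degree_subnetwork: no seed present in the edge list",
            call. = FALSE)
    nodes <- seeds
    sub_edges <- edges[0L, , drop = FALSE]
  } else {
    nb <- unique(unlist(lapply(present, function(s) {
      igraph::neighbors(g, s)$name
    })))
    nodes <- union(seeds, nb)
    keep <- edges$protein_a %in% nodes & edges$protein_b %in% nodes
    sub_edges <- edges[keep, , drop = FALSE]
    rownames(sub_edges) <- NULL
  }
  node_df <- data.frame(protein = nodes, is_seed = nodes %in% seeds,
                        log2fc = NA_real_, has_stq_site = NA,
                        stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    i <- match(node_df$protein, annotations$protein_id)
    if ("log2fc" %in% names(annotations)) node_df$log2fc <- annotations$log2fc[i]
    if ("has_stq_site" %in% names(annotations)) {
      node_df$has_stq_site <- annotations$has_stq_site[i]
    }
  }
  structure(list(nodes = node_df, edges = sub_edges), class = "subnetwork")
}

#' Export a subnetwork as GraphML
#'
#' Writes the subnetwork with node attributes for use in external graph
#' viewers.
#'
#' @param sub a `subnetwork` from [first_degree_subnetwork()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(sub, path) {
  g <- igraph::graph_from_data_frame(sub$edges[, c("protein_a", "protein_b")],
                                     directed = FALSE,
                                     vertices = sub$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
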