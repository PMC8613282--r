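# Orchestration of the two workflows: the cell-line omics response
# (normalise -> differential -> hyperbolic classification -> ranking ->
# gene-set and motif enrichment -> interaction subnetwork) and the in-vivo
# pharmacology summary (caliper volumes -> group TGI; IC50 / combination
# index where dose-response inputs exist). Both run from a single config
# (an R list or a YAML file), log stages to stderr and write a JSON
# manifest recording the seed and a hash of every output.

#' Load a run configuration
#'
#' Accepts an R list or a YAML file path. Referenced input paths are
#' checked for existence up front so a bad path aborts before any
#' computation.
#'
#' @param config named list or path to a YAML file.
#' @return validated configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .fail("config", "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .fail("config", "config must be a list or YAML path")
  for (key in grep("_path$", names(config), value = TRUE)) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) {
      .fail("config", "input path '%s' does not exist: %s", key, p)
    }
  }
  config
}

.write_output <- function(obj, dir, name, manifest) {
  path <- file.path(dir, name)
  write_tsv(obj, path)
  manifest$outputs[[name]] <- unname(tools::md5sum(path))
  manifest
}

#' Run the omics response workflow
#'
#' Executes the full cell-line analysis on count and/or phosphosite inputs:
#' total-signal normalisation (intensities), per-feature differential
#' testing, hyperbolic-threshold classification, ranking, preranked and
#' Fisher gene-set enrichment, S/TQ contingency and position enrichment,
#' and the first-degree interaction subnetwork around proteins with
#' hypophosphorylated sites. Every intermediate table is written to
#' `out_dir` and hashed into the manifest.
#'
#' Config keys (paths may be replaced by in-memory objects of the same
#' shape under the same name without the `_path` suffix):
#' `counts_path` / `counts` (+ `counts_condition`), `phospho_path` /
#' `phospho` (+ `phospho_condition`, `sites`), `gene_sets_path` /
#' `gene_sets`, `edges_path` / `edges` (+ `edge_score_scale`), `n_perm`
#' (default 1000), `seed` (default 1), `out_dir`, `preset_genes` /
#' `preset_phospho` (threshold presets), `min_edge_score` (default 0.7).
#'
#' @param config list or YAML path (see [load_config()]).
#' @return manifest list (also written as `manifest.json` in `out_dir`)
#'   with the seed and md5 hash of every output file; result tables are
#'   attached in `$results`.
#' @export
run_omics <- function(config) {
  cfg <- load_config(config)
  out_dir <- cfg$out_dir %||% tempfile("omics_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  n_perm <- cfg$n_perm %||% 1000L
  manifest <- list(workflow = "omics", seed = seed, outputs = list(),
                   inputs = list(), exclusions = list())
  results <- list()

  gene_sets <- if (!is.null(cfg$gene_sets_path)) read_gmt(cfg$gene_sets_path) else cfg$gene_sets

  # --- RNA-seq branch -------------------------------------------------
  if (!is.null(cfg$counts_path) || !is.null(cfg$counts)) {
    .log("omics: differential expression on counts")
    counts <- if (!is.null(cfg$counts_path)) {
      read_matrix(cfg$counts_path, "counts")
    } else {
      cfg$counts
    }
    cond <- cfg$counts_condition %||% sub("_[0-9]+$", "", colnames(counts))
    de <- fit_differential(counts, cond, "counts")
    de <- classify_hyperbolic(de, hyperbolic_threshold(cfg$preset_genes %||% "genes"))
    manifest <- .write_output(de, out_dir, "de_genes.tsv", manifest)
    results$de_genes <- de
    if (!is.null(gene_sets)) {
      .log("omics: preranked GSEA (%d permutations)", n_perm)
      ranked <- rank_features(de, "stat")
      gsea <- preranked_gsea(ranked, gene_sets, n_perm = n_perm, seed = seed)
      manifest <- .write_output(gsea, out_dir, "gsea_preranked.tsv", manifest)
      results$gsea_preranked <- gsea
      .log("omics: Fisher GSEA on DE genes")
      fg <- fisher_gsea(de$feature_id[de$label != "ns"], de$feature_id, gene_sets)
      manifest <- .write_output(fg, out_dir, "gsea_fisher.tsv", manifest)
      results$gsea_fisher <- fg
    }
  }

  # --- phosphoproteomics branch --------------------------------------
  if (!is.null(cfg$phospho_path) || !is.null(cfg$phospho)) {
    .log("omics: differential phosphorylation")
    intensity <- if (!is.null(cfg$phospho_path)) {
      read_matrix(cfg$phospho_path, "intensity")
    } else {
      cfg$phospho
    }
    intensity <- normalize_total(intensity)
    cond <- cfg$phospho_condition %||% sub("_[0-9]+$", "", colnames(intensity))
    dp <- fit_differential(log2(intensity), cond, "log_intensity")
    dp <- classify_hyperbolic(dp, hyperbolic_threshold(cfg$preset_phospho %||% "phospho"))
    manifest <- .write_output(dp, out_dir, "dp_sites.tsv", manifest)
    results$dp_sites <- dp

    sites <- cfg$sites
    if (!is.null(sites)) {
      cls <- c(up = "hyper", down = "hypo", ns = "non_dp")[dp$label]
      sites <- sites[match(dp$feature_id, sites$protein_id), , drop = FALSE]
      sites$class <- cls
      .log("omics: S/TQ motif enrichment (%d DP, %d non-DP sites)",
           sum(cls != "non_dp"), sum(cls == "non_dp"))
      fg_sites <- sites[sites$class != "non_dp", , drop = FALSE]
      bg_sites <- sites[sites$class == "non_dp", , drop = FALSE]
      if (nrow(fg_sites) > 0L && nrow(bg_sites) > 0L) {
        stq <- contingency_enrichment(fg_sites, bg_sites)
        stq_tab <- data.frame(a = stq$a, b = stq$b, c = stq$c, d = stq$d,
                              odds_ratio = stq$odds_ratio,
                              proportion_ratio = stq$proportion_ratio, p = stq$p)
        manifest <- .write_output(stq_tab, out_dir, "stq_contingency.tsv", manifest)
        results$stq_contingency <- stq
      } else {
        .log("omics: no DP sites; S/TQ contingency skipped")
      }
      hypo_sites <- sites[sites$class == "hypo", , drop = FALSE]
      if (nrow(hypo_sites) > 0L && nrow(bg_sites) > 0L) {
        pe <- position_enrichment(hypo_sites, bg_sites)
        manifest <- .write_output(pe, out_dir, "position_enrichment_hypo.tsv", manifest)
        results$position_enrichment_hypo <- pe
      }
      manifest <- .write_output(sites, out_dir, "sites.tsv", manifest)

      # --- network branch around hypophosphorylated proteins ---------
      edges <- if (!is.null(cfg$edges_path)) {
        read_edges(cfg$edges_path, cfg$edge_score_scale %||% "unit")
      } else {
        cfg$edges
      }
      if (!is.null(edges) && nrow(hypo_sites) > 0L) {
        .log("omics: first-degree subnetwork around %d hypo proteins",
             length(unique(hypo_sites$protein_id)))
        hc <- filter_high_confidence(edges, cfg$min_edge_score %||% 0.7)
        ann <- data.frame(protein_id = dp$feature_id, log2fc = dp$log2fc,
                          has_stq_site = sites$is_stq[match(dp$feature_id,
                                                            sites$protein_id)],
                          stringsAsFactors = FALSE)
        sub <- first_degree_subnetwork(hc, unique(hypo_sites$protein_id), ann)
        manifest <- .write_output(sub$nodes, out_dir, "subnetwork_nodes.tsv", manifest)
        manifest <- .write_output(sub$edges, out_dir, "subnetwork_edges.tsv", manifest)
        results$subnetwork <- sub
      }
    }
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest[c("workflow", "seed", "outputs")], manifest_path,
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$out_dir <- out_dir
  manifest$results <- results
  invisible(manifest)
}

#' Run the in-vivo pharmacology workflow
#'
#' Converts caliper measurements to volumes where needed, computes the
#' group-mean tumour growth inhibition at an endpoint day, and fits IC50s
#' (and a combination index when two-agent data are present) from
#' dose-response inputs.
#'
#' Config keys: `tumor_path` / `tumor` (columns `animal`, `group`, `day`,
#' and either `volume_mm3` or `length_mm` + `width_mm`), `control_group`
#' (default `"control"`), `endpoint_day` (default: last common day),
#' `dose_response` (named list of data.frames with `dose`, `response`),
#' `ci` (list with `d1`, `d2`, `agent1`, `agent2`, `fa_combo`), `out_dir`,
#' `seed`.
#'
#' @param config list or YAML path.
#' @return manifest list with `$results` (`tgi` data.frame, `ic50` named
#'   list of [fit_4pl()] objects, `ci` numeric).
#' @export
run_invivo <- function(config) {
  cfg <- load_config(config)
  out_dir <- cfg$out_dir %||% tempfile("invivo_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(workflow = "invivo", seed = cfg$seed %||% 1L,
                   outputs = list())
  results <- list()

  tum <- if (!is.null(cfg$tumor_path)) read.delim(cfg$tumor_path) else cfg$tumor
  if (!is.null(tum)) {
    if (!"volume_mm3" %in% names(tum)) {
      .log("invivo: converting caliper measurements to volumes")
      tum$volume_mm3 <- caliper_volume(tum$length_mm, tum$width_mm)
    }
    ctrl <- cfg$control_group %||% "control"
    if (!ctrl %in% tum$group) .fail("run_invivo", "control group '%s' not found", ctrl)
    endpoint <- cfg$endpoint_day %||% max(tum$day)
    if (!endpoint %in% tum$day) {
      .fail("run_invivo", "endpoint day %s absent; available: %s", endpoint,
            paste(sort(unique(tum$day)), collapse = ", "))
    }
    day0 <- min(tum$day)
    group_mean <- function(g, d) mean(tum$volume_mm3[tum$group == g & tum$day == d])
    n_animals <- tapply(tum$animal, tum$group, function(a) length(unique(a)))
    small <- names(n_animals)[n_animals < 2]
    if (length(small) > 0L) {
      .log("invivo: group(s) with a single animal: %s", paste(small, collapse = ", "))
    }
    treated_groups <- setdiff(unique(tum$group), ctrl)
    tgi_tab <- do.call(rbind, lapply(treated_groups, function(g) {
      data.frame(group = g,
                 tv0 = group_mean(g, day0), tvt = group_mean(g, endpoint),
                 cv0 = group_mean(ctrl, day0), cvt = group_mean(ctrl, endpoint),
                 stringsAsFactors = FALSE)
    }))
    tgi_tab$tgi_percent <- mapply(tgi, tgi_tab$tv0, tgi_tab$tvt,
                                  tgi_tab$cv0, tgi_tab$cvt)
    .log("invivo: TGI at day %s for %d group(s)", endpoint, nrow(tgi_tab))
    manifest <- .write_output(tgi_tab, out_dir, "tgi.tsv", manifest)
    results$tgi <- tgi_tab
  }

  if (!is.null(cfg$dose_response)) {
    results$ic50 <- lapply(cfg$dose_response, function(dr) {
      fit_4pl(dr$dose, dr$response)
    })
    ic50_tab <- data.frame(agent = names(results$ic50),
                           ic50 = vapply(results$ic50, `[[`, numeric(1), "ic50"),
                           hill = vapply(results$ic50, `[[`, numeric(1), "hill"))
    manifest <- .write_output(ic50_tab, out_dir, "ic50.tsv", manifest)
    if (!is.null(cfg$ci)) {
      ci_cfg <- cfg$ci
      me <- lapply(cfg$dose_response[c(ci_cfg$agent1, ci_cfg$agent2)], function(dr) {
        top <- max(dr$response)
        fa <- clip_fa(1 - dr$response / top)
        fit_median_effect(dr$dose, fa)
      })
      results$ci <- combination_index(ci_cfg$d1, ci_cfg$d2, me[[1L]], me[[2L]],
                                      ci_cfg$fa_combo)
      .log("invivo: combination index = %.3f", results$ci)
    }
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest[c("workflow", "seed", "outputs")], manifest_path,
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$out_dir <- out_dir
  manifest$results <- results
  invisible(manifest)
}
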