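# End-to-end screen: filter -> binarize -> concordance -> pathway screen ->
# compound enrichment (both methods) -> recurrence -> orthogonality ->
# similarity network. Every table lands in out_dir as TSV with a header
# comment carrying the config hash and seed, plus a JSON run manifest.

config_hash <- function(x) {
  sprintf("%08x", hash31(paste(deparse(x), collapse = "")))
}

write_stage_tsv <- function(df, path, hash, seed) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ",")
    }
  }
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# orthoscreen run config=%s seed=%d", hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full screening pipeline
#'
#' Orchestrates every stage over a set of per-cell-line signature matrices:
#' condition/quality filtering, the full-profile concordance screen, the
#' pathway-restricted screen, compound-level enrichment under both methods,
#' the cross-cell-line recurrence filter, the orthogonality screen anchored
#' on the recurrent hits, and the Jaccard similarity network with community
#' detection and centrality metrics. All intermediate tables are written to
#' `out_dir` (TSV with a config-hash/seed header comment) together with a
#' `manifest.json`; identical configs and seeds reproduce every file
#' bit-exactly.
#'
#' @param screens named list (by cell line) of [signature_matrix()] objects
#'   or GCT file paths.
#' @param reference a [build_reference()] profile or reference TSV path.
#' @param gene_sets named list of gene sets or a GMT path.
#' @param out_dir output directory (created if needed).
#' @param moa optional compound-to-MoA table (or TSV path with columns
#'   `compound_id`, `moa`).
#' @param dose,time,tas_min condition filter (defaults 10 uM, 24 h, 0.4).
#' @param z_threshold binarization threshold.
#' @param n_perm permutations for every permutation test.
#' @param fdr_max FDR cutoff for enrichment calls.
#' @param min_lines recurrence threshold (default 3 cell lines).
#' @param combine pathway-label aggregation (`"any"`, `"majority"`, `"all"`).
#' @param os_quantile orthogonality-enrichment quantile criterion.
#' @param edge_threshold similarity threshold for network edges.
#' @param ortho_cell_line cell line whose signatures are aggregated for the
#'   orthogonality stage (default: first).
#' @param seed integer master seed.
#' @param quiet suppress stage messages.
#' @return (invisibly) a list with every stage's tibble plus the manifest.
#' @export
run_full_screen <- function(screens, reference, gene_sets, out_dir,
                            moa = NULL, dose = "10 uM", time = "24 h",
                            tas_min = 0.4, z_threshold = 1, n_perm = 1000,
                            fdr_max = 0.05, min_lines = 3,
                            combine = c("any", "majority", "all"),
                            os_quantile = 0.75, edge_threshold = 0,
                            ortho_cell_line = NULL, seed = 1, quiet = TRUE) {
  combine <- match.arg(combine)
  if (is.character(reference)) reference <- read_reference(reference)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  if (is.character(moa)) moa <- utils::read.delim(moa)
  if (is.null(names(screens)) || any(!nzchar(names(screens)))) {
    stop_bad_arg("`screens` must be a list named by cell line")
  }
  screens <- lapply(screens, function(s) if (is.character(s)) read_gct(s) else s)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(cell_lines = names(screens), dose = dose, time = time,
              tas_min = tas_min, z_threshold = z_threshold, n_perm = n_perm,
              fdr_max = fdr_max, min_lines = min_lines, combine = combine,
              os_quantile = os_quantile, edge_threshold = edge_threshold,
              seed = as.integer(seed))
  hash <- config_hash(cfg)
  emit <- function(df, name) write_stage_tsv(df, file.path(out_dir, name),
                                             hash, as.integer(seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_bad_arg("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  per_line <- lapply(names(screens), function(cl) {
    filt <- stage(paste0("filter:", cl),
                  filter_signatures(screens[[cl]], dose = dose, time = time,
                                    tas_min = tas_min, quiet = quiet))
    conc <- stage(paste0("concordance:", cl),
                  screen_concordance(filt, reference, z_threshold = z_threshold,
                                     n_perm = n_perm,
                                     seed = substream_seed(seed, paste0("conc:", cl)),
                                     quiet = quiet))
    emit(conc, sprintf("concordance_%s.tsv", cl))
    pw <- stage(paste0("pathways:", cl),
                pathway_screen(filt, reference, gene_sets,
                               z_threshold = z_threshold, n_perm = n_perm,
                               seed = substream_seed(seed, paste0("path:", cl)),
                               quiet = quiet))
    emit(pw, sprintf("pathway_%s.tsv", cl))
    enr_full <- stage(paste0("enrich-full:", cl),
                      compound_enrichment(conc, n_perm = n_perm,
                                          seed = substream_seed(seed, paste0("enrf:", cl))))
    emit(enr_full, sprintf("enrichment_full_%s.tsv", cl))
    pw_labels <- stage(paste0("enrich-pathway:", cl),
                       pathway_enrichment_labels(pw, n_perm = n_perm,
                                                 seed = substream_seed(seed, paste0("enrp:", cl)),
                                                 fdr_max = fdr_max, combine = combine))
    emit(pw_labels, sprintf("enrichment_pathway_%s.tsv", cl))
    labels <- dplyr::bind_rows(
      tibble(cell_line = cl, method = "full",
             compound_id = enr_full$compound_id,
             enriched = enr_full$nes > 0 & enr_full$q_value <= fdr_max),
      tibble(cell_line = cl, method = "pathway",
             compound_id = pw_labels$compound_id,
             enriched = pw_labels$enriched))
    list(cell_line = cl, filtered = filt, concordance = conc, pathway = pw,
         enrichment_full = enr_full, pathway_labels = pw_labels,
         labels = labels)
  })
  names(per_line) <- names(screens)

  labels <- dplyr::bind_rows(lapply(per_line, `[[`, "labels"))
  recurrence <- stage("recurrence", recurrent_hits(labels, min_lines = min_lines))
  emit(recurrence, "recurrence.tsv")
  hits <- recurrence$compound_id[recurrence$passes]

  out <- list(per_line = per_line, labels = labels, recurrence = recurrence,
              hits = hits)

  if (length(hits) >= 2) {
    ocl <- ortho_cell_line %||% names(screens)[1]
    agg <- stage("aggregate",
                 aggregate_by_compound(per_line[[ocl]]$filtered,
                                       z_threshold = z_threshold))
    anchors <- agg[, intersect(hits, colnames(agg)), drop = FALSE]
    os_results <- stage("orthogonality",
                        orthogonality_screen(reference, anchors, agg))
    emit(os_results, "orthogonality.tsv")
    enriched_any <- unique(labels$compound_id[labels$enriched &
                                                labels$method == "full"])
    oep <- stage("orthogonality-profile",
                 orthogonality_enrichment_profile(os_results, enriched_any,
                                                  os_quantile = os_quantile))
    emit(as_tibble(as.data.frame(oep), rownames = "anchor_id"),
         "orthogonality_profile.tsv")
    sim <- stage("jaccard", jaccard_matrix(oep))
    net <- stage("network", build_network(sim, edge_threshold = edge_threshold))
    net <- annotate_moa(net, moa)
    communities <- stage("communities", detect_communities(net))
    emit(communities, "communities.tsv")
    cent <- stage("centrality", network_centrality(net))
    emit(cent, "centrality.tsv")
    emit(moa_abundance(net, communities), "moa_abundance.tsv")
    el <- igraph::as_edgelist(net)
    emit(tibble(from = el[, 1], to = el[, 2],
                weight = igraph::E(net)$weight), "edges.tsv")
    write_network_graphml(net, file.path(out_dir, "network.graphml"),
                          communities)
    out <- c(out, list(aggregates = agg, orthogonality = os_results,
                       ortho_profile = oep, similarity = sim, network = net,
                       communities = communities, centrality = cent))
  } else if (!quiet) {
    inform("fewer than two recurrent hits: orthogonality/network stages skipped")
  }

  manifest <- list(package = "orthoscreen",
                   version = as.character(utils::packageVersion("orthoscreen")),
                   config = cfg, config_hash = hash,
                   n_signatures = vapply(per_line,
                     function(l) ncol(l$filtered$values), integer(1)),
                   n_recurrent_hits = length(hits))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
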