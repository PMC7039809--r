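#' Run the full expression-to-regulon pipeline
#'
#' Orchestrates every stage with a single configuration: QC filtering,
#' log-normalization, variable-gene selection, nUMI regression and scaling,
#' PCA, SNN-Louvain clustering, condition composition (when labels are
#' present), cell- and metacell-level regulon activity scoring, the
#' RSS/RSSZ specificity table with the significance rule, AUCZ, CSI module
#' detection, and cluster-to-module connectivity.
#'
#' @param x An [sc_counts] object.
#' @param regulons Named list of regulon gene sets (e.g. from
#'   [read_regulons()]).
#' @param config A [default_config()] list.
#' @param verbose Log stage summaries.
#' @return A named list with elements `counts` (filtered), `qc`, `norm`,
#'   `hvg`, `scaled`, `pca`, `clusters`, `composition` (or `NULL`),
#'   `ras_cells`, `metacells`, `ras_meta`, `specificity`, `aucz`, `csi`,
#'   `modules`, `connectivity`, `config`.
#' @export
run_pipeline <- function(x, regulons, config = default_config(), verbose = FALSE) {
  stopifnot(inherits(x, "sc_counts"))
  cfg <- config

  x <- filter_cells(x, cfg$min_genes, cfg$max_genes, verbose = verbose)
  x <- filter_genes(x, cfg$min_cells, verbose = verbose)
  qc <- cell_qc_stats(x)

  nm <- log_normalize(x, cfg$scale_factor)
  hvg <- find_variable_genes(nm, cfg$hvg_x_low, cfg$hvg_x_high,
                             cfg$hvg_y_cutoff, cfg$hvg_n_bins)
  vlog(verbose, sprintf("%d variable genes selected", sum(hvg$selected)))
  scaled <- regress_and_scale(nm, qc$n_umi, clip = cfg$clip)
  pca <- run_pca(scaled, genes = hvg$gene[hvg$selected], n_pcs = cfg$n_pcs)
  clusters <- cluster_snn_louvain(pca, k_neighbors = cfg$k_neighbors,
                                  resolution = cfg$resolution,
                                  prune = cfg$snn_prune, seed = cfg$seed)
  vlog(verbose, sprintf("%d clusters found", length(unique(clusters))))

  composition <- if (!is.null(x$condition)) {
    cluster_composition(clusters, x$condition)
  }

  rm_cells <- rank_genes(nm, seed = cfg$seed)
  ras_cells <- aucell_score(rm_cells, regulons, cfg$top_fraction)

  meta <- avg20_pool(nm, clusters, pool_size = cfg$pool_size, seed = cfg$seed,
                     verbose = verbose)
  rm_meta <- rank_genes(meta$profiles, seed = cfg$seed)
  ras_meta <- aucell_score(rm_meta, regulons, cfg$top_fraction)

  spec <- specificity_table(ras_cells, clusters,
                            am_meta = ras_meta, meta_clusters = meta$cluster)
  spec <- significant_regulons(spec, cfg$ras_cutoff, cfg$rssz_cutoff)

  aucz <- compute_aucz(ras_cells)
  csi <- compute_csi(ras_meta, delta = cfg$csi_delta)
  modules <- detect_modules(csi, n_modules = cfg$n_modules)
  conn <- connectivity(aucz, clusters, modules, cutoff = cfg$aucz_cutoff)

  list(counts = x, qc = qc, norm = nm, hvg = hvg, scaled = scaled, pca = pca,
       clusters = clusters, composition = composition,
       ras_cells = ras_cells, metacells = meta, ras_meta = ras_meta,
       specificity = spec, aucz = aucz, csi = csi, modules = modules,
       connectivity = conn, config = cfg)
}
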