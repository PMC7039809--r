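#' Default pipeline configuration
#'
#' Collects every numeric threshold used by the pipeline, with the defaults
#' of the workflow it reproduces: QC bounds (200--2500 genes per cell, genes
#' in >= 3 cells), log-normalization to 10,000 counts, variable-gene cutoffs
#' (mean window 0.0125--3, dispersion z >= 0.5), 11 principal components,
#' SNN-Louvain resolution 1.2, Avg20 metacell pooling, AUCell top fraction
#' 0.05, the RAS > 0.2 & RSSZ > 1.0 significance rule, the AUCZ > 2.0
#' connectivity cutoff, CSI margin 0.05, and 3 regulon modules.
#'
#' @param ... Named overrides of individual defaults.
#' @return A named list of class `rscope_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    min_genes = 200, max_genes = 2500, min_cells = 3,
    scale_factor = 10000,
    hvg_x_low = 0.0125, hvg_x_high = 3, hvg_y_cutoff = 0.5, hvg_n_bins = 20,
    clip = 10,
    n_pcs = 11, k_neighbors = 30, snn_prune = 1 / 15, resolution = 1.2,
    min_pct = 0.1, logfc_min = 0.25,
    pool_size = 20, top_fraction = 0.05,
    ras_cutoff = 0.2, rssz_cutoff = 1.0, aucz_cutoff = 2.0,
    csi_delta = 0.05, n_modules = 3,
    seed = 0
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_validation("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "rscope_config")
}

#' Read a YAML configuration file
#'
#' Flat keys named as in [default_config()]; values in the file override the
#' defaults, and further `...` overrides (e.g. from a caller's arguments)
#' take precedence over the file.
#'
#' @param path YAML file path.
#' @param ... Named overrides applied after the file.
#' @return A `rscope_config` list.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(default_config, utils::modifyList(vals, list(...)))
}

validate_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop_validation("config: ", what)
  chk(cfg$min_genes >= 0 && cfg$max_genes >= cfg$min_genes, "gene-count bounds invalid")
  chk(cfg$min_cells >= 0, "min_cells must be >= 0")
  chk(cfg$scale_factor > 0, "scale_factor must be positive")
  chk(cfg$hvg_x_low < cfg$hvg_x_high, "variable-gene mean window empty")
  chk(cfg$hvg_n_bins >= 1, "hvg_n_bins must be >= 1")
  chk(cfg$n_pcs >= 1, "n_pcs must be >= 1")
  chk(cfg$k_neighbors >= 2, "k_neighbors must be >= 2")
  chk(cfg$snn_prune >= 0 && cfg$snn_prune <= 1, "snn_prune must be in [0,1]")
  chk(cfg$resolution > 0, "resolution must be positive")
  chk(cfg$pool_size >= 1, "pool_size must be >= 1")
  chk(cfg$top_fraction > 0 && cfg$top_fraction <= 1, "top_fraction must be in (0,1]")
  chk(cfg$csi_delta >= 0 && cfg$csi_delta < 1, "csi_delta must be in [0,1)")
  chk(cfg$n_modules >= 1, "n_modules must be >= 1")
  chk(is.numeric(cfg$seed) && cfg$seed >= 0 && cfg$seed == floor(cfg$seed),
      "seed must be a nonnegative integer")
  invisible(cfg)
}
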