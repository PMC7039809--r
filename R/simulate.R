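#' Design of a synthetic droplet scRNA-seq experiment
#'
#' Describes a negative-binomial UMI count simulation with planted discrete
#' clusters, cluster-specific regulon programs grouped into correlated
#' modules, per-cluster marker genes, and a two-condition design. The
#' defaults describe the verification scenario used throughout the package:
#' 5 clusters of 400 cells, 2,000 genes, 20 regulons of 20 target genes at
#' 4-fold activation, organized into 3 modules active in clusters 0, 1 and
#' 2 respectively, with NB dispersion 0.5. Clusters 3 and 4 carry marker
#' genes but no regulon program, providing negative controls for the
#' specificity rule.
#'
#' Gene relative abundances are log-normal; library sizes are log-normal
#' around 2,500 UMI. Fold changes act multiplicatively on gene means before
#' library-size scaling (per-cell abundances are renormalized), so
#' normalization must remove library effects. A log-normal activity factor
#' shared by all regulons of a module within each cell induces within-module
#' activity correlation.
#'
#' @param n_clusters,cells_per_cluster,n_genes Dataset dimensions.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of gene
#'   relative abundance.
#' @param lib_meanlog,lib_sdlog Log-normal parameters of per-cell library
#'   size (UMI).
#' @param n_regulons,targets_per_regulon,fold_change Planted regulon
#'   programs; each regulon's gene set includes its TF.
#' @param module_sizes Integer partition of the regulons into modules.
#' @param module_clusters List (one per module) of 0-based cluster ids in
#'   which the module's regulons are active.
#' @param markers_per_cluster,marker_fold Extra cluster-identity genes
#'   (outside any regulon) upregulated in one cluster each.
#' @param target_baseline_quantile Planted program genes (regulon targets
#'   and cluster markers) draw their baseline abundance from above this
#'   quantile of the baseline distribution; network-inferred targets are
#'   necessarily detectably expressed, and silent genes cannot carry a
#'   co-expression signal. Set to 0 for unrestricted baselines.
#' @param dispersion NB dispersion; `variance = mu + dispersion * mu^2`.
#' @param module_noise_sdlog Sd (log scale) of the shared per-module,
#'   per-cell activity factor.
#' @param condition_levels Two condition labels.
#' @param condition_prob Per-cluster probability of the second level
#'   (scalar or length `n_clusters`).
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return A list of class `sim_design`.
#' @export
simulation_design <- function(n_clusters = 5, cells_per_cluster = 400,
                              n_genes = 2000,
                              baseline_meanlog = -1, baseline_sdlog = 0.5,
                              lib_meanlog = log(2500), lib_sdlog = 0.3,
                              n_regulons = 20, targets_per_regulon = 20,
                              fold_change = 4,
                              module_sizes = c(7, 7, 6),
                              module_clusters = list(0, 1, 2),
                              markers_per_cluster = 30, marker_fold = 4,
                              target_baseline_quantile = 0.5,
                              dispersion = 0.5,
                              module_noise_sdlog = 0.25,
                              condition_levels = c("SPF", "GF"),
                              condition_prob = 0.5,
                              seed = 0) {
  d <- as.list(environment())
  if (sum(d$module_sizes) != d$n_regulons) {
    stop_validation("module_sizes must sum to n_regulons")
  }
  if (length(d$module_clusters) != length(d$module_sizes)) {
    stop_validation("module_clusters must have one entry per module")
  }
  if (any(unlist(d$module_clusters) >= d$n_clusters)) {
    stop_validation("module_clusters reference nonexistent clusters")
  }
  planted <- d$n_regulons * d$targets_per_regulon +
    d$n_clusters * d$markers_per_cluster
  if (planted > d$n_genes) {
    stop_validation("more planted program genes (", planted,
                    ") than n_genes (", d$n_genes, ")")
  }
  if (d$fold_change < 1 || d$marker_fold < 1) {
    stop_validation("fold changes must be >= 1")
  }
  if (d$dispersion <= 0) stop_validation("dispersion must be positive")
  if (d$target_baseline_quantile < 0 || d$target_baseline_quantile >= 1) {
    stop_validation("target_baseline_quantile must lie in [0, 1)")
  }
  if (length(d$condition_prob) == 1) {
    d$condition_prob <- rep(d$condition_prob, d$n_clusters)
  }
  if (any(d$condition_prob < 0 | d$condition_prob > 1)) {
    stop_validation("condition_prob must lie in [0,1]")
  }
  structure(d, class = "sim_design")
}

# Core generator: draws counts for given per-cell cluster/condition labels.
# Assumes the RNG is already seeded by the caller.
sim_draw <- function(d, cluster, condition) {
  G <- d$n_genes; C <- length(cluster); K <- d$n_clusters
  gene_ids <- sprintf("g%04d", seq_len(G))
  cell_ids <- sprintf("cell%05d", seq_len(C))

  # planted gene blocks: regulon targets first, then cluster markers
  reg_names <- sprintf("R%02d(+)", seq_len(d$n_regulons))
  reg_module <- rep(seq_along(d$module_sizes), times = d$module_sizes)
  reg_genes <- split(seq_len(d$n_regulons * d$targets_per_regulon),
                     rep(seq_len(d$n_regulons), each = d$targets_per_regulon))
  # first gene of each block doubles as the TF itself
  for (r in seq_len(d$n_regulons)) gene_ids[reg_genes[[r]][1]] <- sprintf("R%02d", r)
  mk_start <- d$n_regulons * d$targets_per_regulon
  marker_genes <- if (d$markers_per_cluster > 0) {
    split(mk_start + seq_len(K * d$markers_per_cluster),
          rep(seq_len(K), each = d$markers_per_cluster))
  } else {
    rep(list(integer()), K)
  }

  mu <- rlnorm(G, d$baseline_meanlog, d$baseline_sdlog)
  q <- d$target_baseline_quantile
  if (q > 0) {
    planted_ix <- seq_len(mk_start + K * d$markers_per_cluster)
    mu[planted_ix] <- stats::qlnorm(runif(length(planted_ix), q, 1),
                                    d$baseline_meanlog, d$baseline_sdlog)
  }
  lib <- rlnorm(C, d$lib_meanlog, d$lib_sdlog)

  f <- matrix(1, G, C)
  s2 <- d$module_noise_sdlog
  for (m in seq_along(d$module_sizes)) {
    z <- rlnorm(C, -s2^2 / 2, s2)  # mean-1 shared activity factor
    active <- cluster %in% d$module_clusters[[m]]
    if (!any(active)) next
    for (r in which(reg_module == m)) {
      f[reg_genes[[r]], active] <- f[reg_genes[[r]], active] *
        (d$fold_change * rep(z[active], each = d$targets_per_regulon))
    }
  }
  for (k in seq_len(K)) {
    in_k <- cluster == (k - 1L)
    if (length(marker_genes[[k]]) && any(in_k)) {
      f[marker_genes[[k]], in_k] <- f[marker_genes[[k]], in_k] * d$marker_fold
    }
  }

  p <- mu * f
  p <- sweep(p, 2, colSums(p), "/")
  means <- sweep(p, 2, lib, "*")
  counts <- matrix(rnbinom(G * C, size = 1 / d$dispersion, mu = means), G, C)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, cell_ids)

  names(cluster) <- names(condition) <- cell_ids
  regulons <- stats::setNames(lapply(reg_genes, function(ix) gene_ids[ix]), reg_names)
  truth <- list(
    cluster = cluster,
    condition = condition,
    regulon_module = stats::setNames(reg_module, reg_names),
    regulon_clusters = stats::setNames(
      lapply(reg_module, function(m) d$module_clusters[[m]]), reg_names),
    module_clusters = d$module_clusters,
    marker_genes = lapply(marker_genes, function(ix) gene_ids[ix]),
    gene_means = stats::setNames(mu, gene_ids)
  )
  list(counts = sc_counts(counts, condition = condition),
       regulons = regulons, truth = truth)
}

#' Simulate a planted-structure UMI count matrix
#'
#' Draws counts under the design: cell (g, c) counts are negative binomial
#' with mean `lib_c * abundance(g, c)`, where a gene's abundance is its
#' baseline times the product of the fold changes of every regulon program
#' active in the cell's cluster (modulated by the module-shared activity
#' factor) and of any marker-gene effect, renormalized within the cell.
#' Conditions are assigned per cell from the design's per-cluster
#' probabilities. The full ground truth is returned alongside the data.
#'
#' @param design A [simulation_design()].
#' @return List with `counts` ([sc_counts]), `regulons` (named list of gene
#'   sets, TF included), and `truth` (cluster/condition labels, regulon
#'   modules and active clusters, marker genes, baseline gene means).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(design$seed, {
    cluster <- rep(0:(design$n_clusters - 1L), each = design$cells_per_cluster)
    pr <- design$condition_prob[cluster + 1L]
    condition <- factor(design$condition_levels[1L + rbinom(length(cluster), 1, pr)],
                        levels = design$condition_levels)
    sim_draw(design, cluster, condition)
  })
}

#' Simulate a condition-dependent composition shift
#'
#' Both conditions draw the same total number of cells, but the second
#' condition's sampling probability for the depleted clusters is reduced by
#' the given fraction (and renormalized), emulating cluster depletion in
#' one colonization state. Realized per-condition cluster proportions are
#' recorded in the truth.
#'
#' @param design A [simulation_design()].
#' @param depleted_clusters 0-based cluster ids depleted in the second
#'   condition level.
#' @param depletion Fractional reduction in `[0, 1)`; 0 is a no-op.
#' @return As [simulate_counts()], with `truth$realized_proportions`
#'   (clusters x conditions) added.
#' @export
simulate_condition_shift <- function(design, depleted_clusters, depletion) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.numeric(depletion) || length(depletion) != 1 ||
      depletion < 0 || depletion >= 1) {
    stop_validation("depletion must lie in [0, 1)")
  }
  if (any(!depleted_clusters %in% 0:(design$n_clusters - 1L))) {
    stop_validation("depleted_clusters reference nonexistent clusters")
  }
  with_seed(design$seed, {
    K <- design$n_clusters
    n_per_cond <- (K * design$cells_per_cluster) %/% 2L
    pA <- rep(1 / K, K)
    pB <- pA
    pB[depleted_clusters + 1L] <- pB[depleted_clusters + 1L] * (1 - depletion)
    pB <- pB / sum(pB)
    clA <- sample(0:(K - 1L), n_per_cond, replace = TRUE, prob = pA)
    clB <- sample(0:(K - 1L), n_per_cond, replace = TRUE, prob = pB)
    cluster <- c(clA, clB)
    condition <- factor(rep(design$condition_levels, each = n_per_cond),
                        levels = design$condition_levels)
    out <- sim_draw(design, cluster, condition)
    out$truth$realized_proportions <- prop.table(
      table(cluster = cluster, condition = condition), margin = 2)
    out$truth$depleted_clusters <- sort(unique(depleted_clusters))
    out$truth$depletion <- depletion
    out
  })
}
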