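#' Principal component analysis of scaled expression
#'
#' Exact PCA of cells in the space of the supplied (typically variable)
#' genes. Loadings are orthonormal and each component's sign is fixed so
#' that its largest-magnitude loading is positive, making results
#' deterministic.
#'
#' @param scaled Dense genes-by-cells matrix of scaled residuals.
#' @param genes Optional character vector restricting to selected genes.
#' @param n_pcs Number of components to return.
#' @return List of class `sc_pca`: `coords` (cells x n_pcs scores),
#'   `loadings` (genes x n_pcs), `variance` (per-PC variance, non-increasing).
#' @export
run_pca <- function(scaled, genes = NULL, n_pcs = 11) {
  m <- as_dense(scaled)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) stop_validation("genes absent from matrix: ", missing[1])
    m <- m[genes, , drop = FALSE]
  }
  if (n_pcs > min(dim(m))) {
    stop_validation("n_pcs exceeds matrix rank bound min(genes, cells)")
  }
  p <- prcomp(t(m), center = TRUE, scale. = FALSE, rank. = n_pcs)
  vars <- c(p$sdev^2, numeric(n_pcs))[seq_len(n_pcs)]
  if (any(vars < 1e-10)) {
    warning("run_pca: trailing components have ~zero variance (rank-deficient input)")
  }
  flip <- vapply(seq_len(n_pcs), function(j) {
    w <- p$rotation[, j]
    if (w[which.max(abs(w))] < 0) -1 else 1
  }, 1)
  coords <- sweep(p$x[, seq_len(n_pcs), drop = FALSE], 2, flip, "*")
  loadings <- sweep(p$rotation[, seq_len(n_pcs), drop = FALSE], 2, flip, "*")
  colnames(coords) <- colnames(loadings) <- paste0("PC", seq_len(n_pcs))
  rownames(coords) <- colnames(m)
  structure(list(coords = coords, loadings = loadings, variance = vars),
            class = "sc_pca")
}

#' SNN graph construction and Louvain clustering
#'
#' Builds a k-nearest-neighbor graph on Euclidean distances in PC space
#' (each cell's neighbor list includes itself), converts it to a
#' shared-nearest-neighbor graph whose edge weights are the Jaccard overlap
#' of neighbor lists, prunes edges below `prune`, and optimizes modularity
#' with the Louvain algorithm at the given resolution. Cluster ids are
#' relabeled 0..K-1 by decreasing cluster size for determinism.
#'
#' @param emb An `sc_pca` object or a cells-by-dims coordinate matrix.
#' @param k_neighbors Neighborhood size (including the cell itself).
#' @param resolution Louvain modularity resolution.
#' @param prune Jaccard cutoff below which SNN edges are removed.
#' @param seed RNG seed for Louvain tie-breaking.
#' @return Named integer vector of cluster ids (0-based), one per cell.
#' @export
cluster_snn_louvain <- function(emb, k_neighbors = 30, resolution = 1.2,
                                prune = 1 / 15, seed = 0) {
  coords <- if (inherits(emb, "sc_pca")) emb$coords else as.matrix(emb)
  n <- nrow(coords)
  if (k_neighbors >= n) stop_validation("k_neighbors must be smaller than the number of cells")

  d <- as.matrix(stats::dist(coords))
  nbr <- matrix(0L, n, k_neighbors)
  for (i in seq_len(n)) {
    nbr[i, ] <- order(d[i, ])[seq_len(k_neighbors)]  # self has distance 0
  }
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                            j = as.integer(t(nbr)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j
  ii <- shared@i[keep] + 1L; jj <- shared@j[keep] + 1L; sh <- shared@x[keep]
  jac <- sh / (2 * k_neighbors - sh)
  ok <- jac >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = ii[ok], to = jj[ok], weight = jac[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(cl)[as.character(seq_len(n))]
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  out <- as.integer(relab[as.character(memb)])
  names(out) <- rownames(coords)
  out
}

#' Condition composition of clusters
#'
#' For every cluster x condition cell count it reports the raw percentage of
#' the cluster's cells and a condition-size-normalized percentage: counts
#' are first divided by the condition's total cell number, then renormalized
#' within each cluster to sum to 100. The normalized column is the fair
#' comparison when conditions were sampled to different depths.
#'
#' @param clusters Named integer vector of cluster ids per cell.
#' @param condition Per-cell condition labels (same order/length).
#' @return Data frame with `cluster`, `condition`, `count`, `pct`, `norm_pct`.
#' @export
cluster_composition <- function(clusters, condition) {
  if (length(clusters) != length(condition)) {
    stop_validation("clusters and condition must have equal length")
  }
  condition <- factor(condition)
  if (nlevels(condition) < 1) stop_validation("condition needs at least one level")
  tab <- table(cluster = clusters, condition = condition)
  cond_tot <- colSums(tab)
  raw_pct <- 100 * sweep(tab, 1, rowSums(tab), "/")
  norm <- sweep(tab, 2, cond_tot, "/")
  norm_pct <- 100 * sweep(norm, 1, rowSums(norm), "/")
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df$pct <- as.vector(raw_pct)
  df$norm_pct <- as.vector(norm_pct)
  names(df) <- c("cluster", "condition", "count", "pct", "norm_pct")
  df$cluster <- type.convert(df$cluster, as.is = TRUE)
  df[order(df$cluster, df$condition), , drop = FALSE]
}

#' Flag clusters depleted in one condition
#'
#' Uses the condition-size-normalized shares from [cluster_composition()]:
#' a cluster is flagged as depleted in `level` when that condition's
#' normalized share falls below `(1 - min_depletion)` times the share
#' expected under no compositional change (equal normalized shares across
#' levels).
#'
#' @param comp Output of [cluster_composition()].
#' @param level Condition level tested for depletion.
#' @param min_depletion Minimum relative reduction to call depletion.
#' @return Data frame with `cluster`, `norm_share`, `expected_share`,
#'   `depleted`.
#' @export
flag_composition_shift <- function(comp, level, min_depletion = 1 / 3) {
  if (!level %in% comp$condition) stop_validation("level not present: ", level)
  n_lev <- length(unique(comp$condition))
  expected <- 1 / n_lev
  sub <- comp[comp$condition == level, , drop = FALSE]
  share <- sub$norm_pct / 100
  data.frame(cluster = sub$cluster,
             norm_share = share,
             expected_share = expected,
             depleted = share < expected * (1 - min_depletion),
             stringsAsFactors = FALSE, row.names = NULL)
}
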