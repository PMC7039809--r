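# Entropy (base 2) of a probability vector; 0 log 0 = 0.
entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Jensen-Shannon divergence between probability vectors, base-2 logs,
# bounded in [0, 1].
jsd2 <- function(p, q) {
  m <- (p + q) / 2
  j <- entropy2(m) - (entropy2(p) + entropy2(q)) / 2
  min(max(j, 0), 1)  # clip numerical noise at the boundaries
}

#' Regulon specificity score (RSS)
#'
#' For each regulon and cluster, compares the regulon's cell-level activity
#' distribution `P` (RAS normalized to sum 1 over all cells) with the
#' cluster's indicator distribution `Q` (uniform over the cluster's cells)
#' via the Jensen-Shannon divergence with base-2 logarithms, and reports
#' `rss = 1 - sqrt(JSD)`. RSS is 1 exactly when activity is uniformly
#' concentrated on the cluster, and is invariant to positive rescaling of
#' the activity row. All-zero activity rows are emitted as `NA` with a
#' warning.
#'
#' @param am Activity matrix on single cells (regulons x cells).
#' @param clusters Cluster assignment for the columns of `am`.
#' @return Matrix (regulons x clusters) of RSS values in [0, 1].
#' @export
compute_rss <- function(am, clusters) {
  if (length(clusters) != ncol(am)) {
    stop_validation("clusters must cover every column of the activity matrix")
  }
  ids <- sort(unique(clusters))
  out <- matrix(NA_real_, nrow(am), length(ids),
                dimnames = list(rownames(am), as.character(ids)))
  zero_rows <- rowSums(am) == 0
  if (any(zero_rows)) {
    warning("all-zero activity rows emitted as NA: ",
            paste(rownames(am)[zero_rows], collapse = ", "))
  }
  q_list <- lapply(ids, function(k) {
    q <- as.numeric(clusters == k)
    q / sum(q)
  })
  for (r in seq_len(nrow(am))) {
    if (zero_rows[r]) next
    p <- am[r, ] / sum(am[r, ])
    for (j in seq_along(ids)) {
      out[r, j] <- 1 - sqrt(jsd2(p, q_list[[j]]))
    }
  }
  out
}

#' Z-score RSS across regulons within each cluster (RSSZ)
#'
#' Within every cluster column, standardizes RSS across regulons with the
#' population (divide-by-n) standard deviation; zero-variance columns map
#' to zero.
#'
#' @param rss RSS matrix (regulons x clusters) from [compute_rss()].
#' @return Matrix of the same shape.
#' @export
compute_rssz <- function(rss) {
  if (nrow(rss) < 2) stop_validation("RSSZ needs at least 2 regulons")
  out <- apply(rss, 2, zscore_pop)
  dimnames(out) <- dimnames(rss)
  out
}

#' Assemble the per-(regulon, cluster) specificity table
#'
#' Combines RSS, RSSZ and the cluster-level mean activity. The mean is taken
#' over the cluster's Avg20 metacells when a [avg20_pool()] activity matrix
#' is supplied (the denoised representation the specificity plots derive
#' from), or over single cells otherwise.
#'
#' @param am_cells Activity matrix on cells.
#' @param clusters Cluster assignment for the cells.
#' @param am_meta Optional activity matrix on metacells.
#' @param meta_clusters Cluster assignment for the metacell columns
#'   (required with `am_meta`).
#' @return Data frame with `regulon`, `cluster`, `rss`, `rssz`, `mean_ras`.
#' @export
specificity_table <- function(am_cells, clusters, am_meta = NULL,
                              meta_clusters = NULL) {
  rss <- compute_rss(am_cells, clusters)
  rssz <- compute_rssz(rss)
  ids <- colnames(rss)
  if (!is.null(am_meta)) {
    if (is.null(meta_clusters) || length(meta_clusters) != ncol(am_meta)) {
      stop_validation("meta_clusters must cover every metacell column")
    }
    src <- am_meta; src_cl <- as.character(meta_clusters)
  } else {
    src <- am_cells; src_cl <- as.character(clusters)
  }
  mean_ras <- vapply(ids, function(k) {
    rowMeans(src[, src_cl == k, drop = FALSE])
  }, numeric(nrow(src)))
  mean_ras <- mean_ras[rownames(rss), , drop = FALSE]
  df <- data.frame(
    regulon = rep(rownames(rss), times = ncol(rss)),
    cluster = rep(ids, each = nrow(rss)),
    rss = as.vector(rss),
    rssz = as.vector(rssz),
    mean_ras = as.vector(mean_ras),
    stringsAsFactors = FALSE, row.names = NULL
  )
  df$cluster <- type.convert(df$cluster, as.is = TRUE)
  df
}

#' Flag cluster-specific regulons
#'
#' A (regulon, cluster) pair is significant when both cutoffs are strictly
#' exceeded: cluster-level mean activity above `ras_cutoff` and RSSZ above
#' `rssz_cutoff`. Rows are sorted by decreasing RSSZ within cluster.
#'
#' @param spec Output of [specificity_table()].
#' @param ras_cutoff Strict lower bound on mean activity (default 0.2).
#' @param rssz_cutoff Strict lower bound on RSSZ (default 1.0).
#' @return The table with a logical `significant` column, sorted.
#' @export
significant_regulons <- function(spec, ras_cutoff = 0.2, rssz_cutoff = 1.0) {
  spec$significant <- !is.na(spec$rss) &
    spec$mean_ras > ras_cutoff & spec$rssz > rssz_cutoff
  spec[order(spec$cluster, -spec$rssz), , drop = FALSE]
}

# CSI from a precomputed correlation matrix: csi(a,b) = fraction of other
# regulons c whose correlation with BOTH a and b falls below pcc(a,b) - delta.
csi_from_cor <- function(pcc, delta) {
  N <- nrow(pcc)
  csi <- matrix(0, N, N, dimnames = dimnames(pcc))
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      if (a == b) { csi[a, b] <- 1; next }
      thr <- pcc[a, b] - delta
      others <- setdiff(seq_len(N), c(a, b))
      csi[a, b] <- sum(pcc[a, others] < thr & pcc[b, others] < thr) / (N - 2)
    }
  }
  csi
}

#' Connection specificity index of regulon pairs
#'
#' Computes Pearson correlations of regulon activities over metacell
#' columns, then for each pair (a, b) the fraction of the other N - 2
#' regulons whose correlation with both a and b is below `pcc(a,b) - delta`.
#' High CSI marks pairs whose association is specific rather than part of a
#' diffuse correlation background. The diagonal is fixed at 1; the matrix is
#' symmetric by construction. Constant activity rows (undefined correlation)
#' are excluded with a warning.
#'
#' @param am Activity matrix on metacells (>= 3 regulons, >= 3 columns).
#' @param delta Correlation margin (default 0.05).
#' @return List-free symmetric CSI matrix in [0, 1] with attribute `pcc`.
#' @export
compute_csi <- function(am, delta = 0.05) {
  if (nrow(am) < 3) stop_validation("CSI needs at least 3 regulons")
  if (ncol(am) < 3) stop_validation("CSI needs at least 3 columns")
  sds <- apply(am, 1, sd)
  if (any(sds == 0)) {
    warning("constant activity rows excluded from CSI: ",
            paste(rownames(am)[sds == 0], collapse = ", "))
    am <- am[sds > 0, , drop = FALSE]
    if (nrow(am) < 3) stop_validation("fewer than 3 regulons with variable activity")
  }
  pcc <- cor(t(am))
  csi <- csi_from_cor(pcc, delta)
  attr(csi, "pcc") <- pcc
  csi
}

#' Detect regulon modules by hierarchical clustering of CSI
#'
#' Average-linkage agglomerative clustering on the distance `1 - CSI`, cut
#' into `n_modules` groups. Module ids are relabeled 1..n by decreasing
#' module size.
#'
#' @param csi CSI matrix from [compute_csi()].
#' @param n_modules Number of modules to cut (<= number of regulons).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return Named integer vector mapping each regulon to a module id.
#' @export
detect_modules <- function(csi, n_modules = 3, linkage = "average") {
  N <- nrow(csi)
  if (n_modules > N) stop_validation("n_modules exceeds the number of regulons")
  hc <- hclust(as.dist(1 - csi), method = linkage)
  raw <- cutree(hc, k = n_modules)
  sizes <- sort(table(raw), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relab[as.character(raw)])
  names(out) <- rownames(csi)
  out
}

#' Split one module into sub-modules
#'
#' Re-runs [detect_modules()] on the CSI submatrix of a single module's
#' regulons.
#'
#' @param csi Full CSI matrix.
#' @param modules Module assignment from [detect_modules()].
#' @param module Module id to split.
#' @param n_sub Number of sub-modules.
#' @param linkage Agglomeration method.
#' @return Named integer vector over the module's regulons.
#' @export
detect_submodules <- function(csi, modules, module, n_sub, linkage = "average") {
  members <- names(modules)[modules == module]
  if (length(members) < n_sub) stop_validation("module smaller than n_sub")
  detect_modules(csi[members, members, drop = FALSE], n_modules = n_sub,
                 linkage = linkage)
}

#' Cluster-to-module connectivity flows
#'
#' A cell's module-level activity z-score is the mean of its AUCZ values
#' over the module's regulons; for every (cluster, module) pair the table
#' counts cells whose module-level AUCZ strictly exceeds `cutoff`. The
#' `fraction` column normalizes counts within each cluster across modules
#' (zero when a cluster has no counted cell), giving Sankey-ready flows.
#'
#' @param aucz AUCZ matrix on single cells from [compute_aucz()].
#' @param clusters Cluster assignment for the cells.
#' @param modules Module assignment from [detect_modules()].
#' @param cutoff Strict AUCZ threshold (default 2.0).
#' @return Data frame with `cluster`, `module`, `count`, `fraction`.
#' @export
connectivity <- function(aucz, clusters, modules, cutoff = 2.0) {
  if (length(clusters) != ncol(aucz)) {
    stop_validation("clusters must cover every column of the AUCZ matrix")
  }
  mod_ids <- sort(unique(modules))
  cl_ids <- sort(unique(clusters))
  rows <- list()
  for (m in mod_ids) {
    members <- intersect(names(modules)[modules == m], rownames(aucz))
    if (!length(members)) {
      warning("module ", m, " has no scored regulons; zero row emitted")
      mod_z <- rep(-Inf, ncol(aucz))
    } else {
      mod_z <- colMeans(aucz[members, , drop = FALSE])
    }
    above <- mod_z > cutoff
    for (k in cl_ids) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, module = m, count = sum(above & clusters == k),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  tot <- stats::ave(df$count, df$cluster, FUN = sum)
  df$fraction <- ifelse(tot > 0, df$count / tot, 0)
  df[order(df$cluster, df$module), , drop = FALSE]
}
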