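#' Per-cell gene ranking
#'
#' Ranks genes within each cell by decreasing expression (rank 1 = highest).
#' Ties are broken by a single seeded global gene permutation applied
#' identically to every cell, so repeated scoring is stable and all-zero
#' cells get the same (arbitrary but fixed) ordering.
#'
#' @param nm Expression matrix (genes x cells); any monotone transform of
#'   counts gives identical ranks.
#' @param seed Seed for the global tie-break permutation.
#' @return Integer matrix of ranks (genes x cells); each column is a
#'   permutation of `1..n_genes`.
#' @export
rank_genes <- function(nm, seed = 0) {
  m <- as_dense(nm)
  if (nrow(m) < 1) stop_validation("rank_genes needs at least one gene")
  tie_break <- with_seed(seed, sample.int(nrow(m)))
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (c in seq_len(ncol(m))) {
    ord <- order(-m[, c], tie_break)
    out[ord, c] <- seq_len(nrow(m))
  }
  out
}

#' Regulon activity scores by recovery-curve AUC
#'
#' For each regulon and cell, builds the recovery curve
#' `rc(x) = #\{genes of the regulon with rank <= x\}` over the top
#' `T = ceiling(top_fraction * n_genes)` positions of the cell's gene
#' ranking, and reports the area under the curve normalized by the maximal
#' achievable area `sum_x min(x, m)` for a regulon with `m` genes in the
#' universe -- so RAS lies in [0, 1] regardless of regulon size. Regulon
#' genes absent from the matrix universe are intersected away; regulons
#' with no gene left are skipped with a warning.
#'
#' @param rm Rank matrix from [rank_genes()].
#' @param regulons Named list of gene-id vectors.
#' @param top_fraction Fraction of the ranking that defines the recovery
#'   window (default 0.05).
#' @return Activity matrix (regulons x cells) with values in [0, 1] and
#'   attribute `top_fraction`.
#' @export
aucell_score <- function(rm, regulons, top_fraction = 0.05) {
  n_genes <- nrow(rm)
  T_ <- ceiling(top_fraction * n_genes)
  if (T_ < 1) stop_validation("top window is empty; increase top_fraction")
  universe <- rownames(rm)
  keep <- vapply(regulons, function(g) length(intersect(g, universe)) > 0, TRUE)
  if (any(!keep)) {
    warning("regulons with no gene in the universe skipped: ",
            paste(names(regulons)[!keep], collapse = ", "))
  }
  regulons <- regulons[keep]
  out <- matrix(NA_real_, length(regulons), ncol(rm),
                dimnames = list(names(regulons), colnames(rm)))
  for (i in seq_along(regulons)) {
    genes <- intersect(regulons[[i]], universe)
    m <- length(genes)
    denom <- sum(pmin(seq_len(T_), m))
    r <- rm[genes, , drop = FALSE]
    contrib <- pmax(T_ - r + 1L, 0L)  # sum_x 1{rank<=x} over x = rank..T
    out[i, ] <- colSums(contrib) / denom
  }
  attr(out, "top_fraction") <- top_fraction
  out
}

#' Pool cells into within-cluster metacells (Avg20)
#'
#' Within each cluster, cells are shuffled with the given seed and split
#' into consecutive disjoint pools of `pool_size`; leftover cells are
#' dropped (and logged), except that a cluster smaller than `pool_size`
#' contributes a single pool of all its cells. Each metacell profile is the
#' per-gene arithmetic mean of the pooled cells' normalized expression.
#'
#' @param nm Log-normalized matrix (genes x cells).
#' @param clusters Named integer cluster assignment for the columns of `nm`.
#' @param pool_size Cells per pool (default 20).
#' @param seed Seed for the within-cluster shuffle.
#' @param verbose Log pool and leftover counts.
#' @return List of class `metacells`: `profiles` (genes x metacells),
#'   `cluster` (metacell to cluster map), `cells` (list of pooled cell ids),
#'   `pool_size`.
#' @export
avg20_pool <- function(nm, clusters, pool_size = 20, seed = 0, verbose = FALSE) {
  m <- as_dense(nm)
  if (length(clusters) != ncol(m)) {
    stop_validation("clusters must cover every column of the matrix")
  }
  ids <- sort(unique(clusters))
  profiles <- list(); mc_cluster <- integer(); mc_cells <- list()
  with_seed(seed, {
    for (k in ids) {
      cells <- which(clusters == k)
      if (!length(cells)) next
      cells <- cells[sample.int(length(cells))]
      if (length(cells) < pool_size) {
        pools <- list(cells)
      } else {
        n_pools <- length(cells) %/% pool_size
        dropped <- length(cells) - n_pools * pool_size
        if (dropped > 0) {
          vlog(verbose, sprintf("avg20_pool: cluster %s: %d leftover cells dropped",
                                k, dropped))
        }
        pools <- split(cells[seq_len(n_pools * pool_size)],
                       rep(seq_len(n_pools), each = pool_size))
      }
      for (p in pools) {
        profiles[[length(profiles) + 1L]] <- rowMeans(m[, p, drop = FALSE])
        mc_cluster[[length(mc_cluster) + 1L]] <- k
        mc_cells[[length(mc_cells) + 1L]] <- colnames(m)[p]
      }
    }
  })
  prof <- do.call(cbind, profiles)
  colnames(prof) <- sprintf("mc%04d", seq_len(ncol(prof)))
  rownames(prof) <- rownames(m)
  names(mc_cluster) <- colnames(prof)
  structure(list(profiles = prof, cluster = mc_cluster, cells = mc_cells,
                 pool_size = pool_size), class = "metacells")
}

#' Z-score regulon activities across cells (AUCZ)
#'
#' Standardizes each regulon's activity row across columns using the
#' population (divide-by-n) standard deviation; constant rows map to zero.
#'
#' @param am Activity matrix (regulons x cells or metacells), >= 2 columns.
#' @return Matrix of the same shape with row mean 0 and population sd 1
#'   (or all zeros for constant rows).
#' @export
compute_aucz <- function(am) {
  if (ncol(am) < 2) stop_validation("AUCZ needs at least 2 columns")
  out <- t(apply(am, 1, zscore_pop))
  dimnames(out) <- dimnames(am)
  out
}
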