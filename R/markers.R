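#' Two-sample Wilcoxon rank-sum test
#'
#' Mann-Whitney U test between two groups of expression values. For small
#' tie-free samples (`min(|A|, |B|) <= exact_limit`) the exact null
#' distribution is used; otherwise the tie-corrected normal approximation
#' with continuity correction. Fully tied samples (zero rank variance)
#' return p = 1.
#'
#' @param x,y Numeric value vectors for the two groups (each nonempty).
#' @param exact_limit Largest `min(|A|, |B|)` for which the exact
#'   distribution is used (tie-free data only).
#' @return List with `statistic` (U for the first group) and `p.value`.
#' @export
wilcoxon_test <- function(x, y, exact_limit = 8) {
  if (!length(x) || !length(y)) stop_validation("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_limit
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  p <- res$p.value
  if (is.na(p) || is.nan(p)) p <- 1  # degenerate: zero rank variance (all tied)
  list(statistic = unname(res$statistic), p.value = min(p, 1))
}

# Fast vectorized rank-sum p-values for a genes x cells matrix and a binary
# grouping; tie-corrected normal approximation with continuity correction.
# Used by the marker scans, where groups are large.
rank_sum_pvals <- function(m, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  pv <- numeric(nrow(m))
  for (g in seq_len(nrow(m))) {
    r <- rank(m[g, ])
    W <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    nt <- table(m[g, ])
    tiecor <- sum(nt^3 - nt) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tiecor)
    if (sigma2 <= 0) { pv[g] <- 1; next }
    z <- W - n1 * n2 / 2
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)
    pv[g] <- min(2 * stats::pnorm(-abs(z)), 1)
  }
  pv
}

marker_scan <- function(nm, in_group, out_group, min_pct, logfc_min,
                        positive_only) {
  m <- as_dense(nm)
  a <- m[, in_group, drop = FALSE]
  b <- m[, out_group, drop = FALSE]
  pct_in <- rowMeans(a > 0)
  pct_out <- rowMeans(b > 0)
  mean_in <- rowMeans(expm1(a))
  mean_out <- rowMeans(expm1(b))
  logfc <- log((mean_in + 1) / (mean_out + 1))
  pass_pct <- pmax(pct_in, pct_out) >= min_pct
  pass_fc <- if (positive_only) logfc >= logfc_min else abs(logfc) >= logfc_min
  tested <- which(pass_pct & pass_fc)
  if (!length(tested)) {
    warning("no genes pass the expression filters")
    return(data.frame(gene = character(), logfc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  }
  sub <- m[tested, c(which(in_group), which(out_group)), drop = FALSE]
  grp <- c(rep(TRUE, sum(in_group)), rep(FALSE, sum(out_group)))
  pv <- rank_sum_pvals(sub, grp)
  out <- data.frame(gene = rownames(m)[tested],
                    logfc = logfc[tested],
                    pct_in = pct_in[tested],
                    pct_out = pct_out[tested],
                    p = pv,
                    p_adj = pmin(pv * length(tested), 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p, -out$logfc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positive cluster markers by Wilcoxon rank-sum test
#'
#' Tests each gene in one cluster against all remaining cells. Only genes
#' detected in at least `min_pct` of either group and with log fold change
#' (natural log of the ratio of mean back-transformed expression + 1) of at
#' least `logfc_min` are tested; p-values are Bonferroni-adjusted over the
#' genes tested. Rows are sorted by p, then by decreasing log fold change.
#'
#' @param nm Log-normalized matrix (genes x cells).
#' @param clusters Named integer cluster assignment covering the cells.
#' @param cluster Cluster id to profile, or `NULL` for all clusters (adds a
#'   `cluster` column).
#' @param min_pct Minimum detection fraction in either group.
#' @param logfc_min Minimum log fold change (positive markers only).
#' @return Marker data frame (`gene`, `logfc`, `pct_in`, `pct_out`, `p`,
#'   `p_adj`, and `cluster` when scanning all).
#' @export
find_markers <- function(nm, clusters, cluster = NULL, min_pct = 0.1,
                         logfc_min = 0.25) {
  ids <- sort(unique(clusters))
  if (length(ids) < 2) stop_validation("marker detection needs at least 2 clusters")
  if (is.null(cluster)) {
    res <- lapply(ids, function(k) {
      tab <- find_markers(nm, clusters, cluster = k, min_pct = min_pct,
                          logfc_min = logfc_min)
      if (nrow(tab)) tab$cluster <- k
      tab
    })
    res <- res[vapply(res, nrow, 1L) > 0]
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    return(out)
  }
  if (!cluster %in% ids) stop_validation("cluster not present: ", cluster)
  in_group <- clusters == cluster
  marker_scan(nm, in_group, !in_group, min_pct, logfc_min, positive_only = TRUE)
}

#' Condition-wise differential expression within selected clusters
#'
#' Compares the two condition levels among cells of the given clusters with
#' the same test and expression filters as [find_markers()], but keeping
#' genes changed in either direction (signed log fold change, first level
#' versus second).
#'
#' @param nm Log-normalized matrix.
#' @param clusters Cluster assignment per cell.
#' @param which_clusters Cluster ids to restrict to.
#' @param condition Per-cell condition factor with exactly 2 levels.
#' @param min_pct,logfc_min Expression filters as in [find_markers()].
#' @return Marker data frame with signed `logfc`.
#' @export
condition_de <- function(nm, clusters, which_clusters, condition,
                         min_pct = 0.1, logfc_min = 0.25) {
  condition <- factor(condition)
  if (nlevels(condition) != 2) stop_validation("condition must have exactly 2 levels")
  sel <- clusters %in% which_clusters
  if (!any(sel)) stop_validation("no cells in the selected clusters")
  cond_sel <- droplevels(condition[sel])
  if (nlevels(cond_sel) < 2) {
    stop_validation("a condition level is absent from the selected clusters")
  }
  sub <- as_dense(nm)[, sel, drop = FALSE]
  in_group <- cond_sel == levels(cond_sel)[1]
  marker_scan(sub, in_group, !in_group, min_pct, logfc_min, positive_only = FALSE)
}

#' Per-cluster average expression
#'
#' Mean of back-transformed normalized values per cluster, re-logged --
#' the summary used for cluster-level expression heatmaps.
#'
#' @param nm Log-normalized matrix.
#' @param clusters Cluster assignment per cell.
#' @return Genes x clusters matrix of `ln(1 + mean(e^x - 1))`.
#' @export
average_expression <- function(nm, clusters) {
  m <- expm1(as_dense(nm))
  ids <- sort(unique(clusters))
  out <- vapply(ids, function(k) rowMeans(m[, clusters == k, drop = FALSE]),
                numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m))
  colnames(out) <- as.character(ids)
  rownames(out) <- rownames(nm)
  log1p(out)
}
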