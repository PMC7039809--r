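# Independent brute-force oracles used to verify the analytical code paths.
# These deliberately re-derive each quantity from its definition rather than
# reusing any package internals.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Recovery-curve AUC by direct enumeration of the curve.
oracle_auc <- function(regulon_ranks, n_genes, top_fraction) {
  T_ <- ceiling(top_fraction * n_genes)
  m <- length(regulon_ranks)
  rc <- vapply(seq_len(T_), function(x) sum(regulon_ranks <= x), 1)
  sum(rc) / sum(pmin(seq_len(T_), m))
}

# Exact two-sided Mann-Whitney p by enumeration of all rank assignments
# (tie-free data only).
oracle_wilcox_exact <- function(x, y) {
  stopifnot(anyDuplicated(c(x, y)) == 0)
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(N, m)
  U <- colSums(matrix(seq_len(N)[splits], nrow = m)) - m * (m + 1) / 2
  p <- if (u_obs > m * n / 2) 2 * mean(U >= u_obs) else 2 * mean(U <= u_obs)
  min(p, 1)
}

# Jensen-Shannon divergence from its definition (base-2 logs).
oracle_jsd <- function(p, q) {
  H <- function(w) { w <- w[w > 0]; -sum(w * log2(w)) }
  H((p + q) / 2) - (H(p) + H(q)) / 2
}

oracle_rss <- function(ras, indicator) {
  p <- ras / sum(ras)
  q <- indicator / sum(indicator)
  1 - sqrt(oracle_jsd(p, q))
}

# CSI by direct triple-loop counting over the correlation matrix.
oracle_csi <- function(pcc, delta) {
  N <- nrow(pcc)
  out <- matrix(1, N, N, dimnames = dimnames(pcc))
  for (a in seq_len(N)) for (b in seq_len(N)) {
    if (a == b) next
    cnt <- 0
    for (c in seq_len(N)) {
      if (c == a || c == b) next
      if (pcc[a, c] < pcc[a, b] - delta && pcc[b, c] < pcc[a, b] - delta) {
        cnt <- cnt + 1
      }
    }
    out[a, b] <- cnt / (N - 2)
  }
  out
}

# A tiny normalized-expression-like matrix with dimnames.
make_nm <- function(values, n_genes = NULL, n_cells = NULL) {
  m <- matrix(values, nrow = n_genes %||% nrow(values), ncol = n_cells %||% ncol(values))
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Counts container from a plain matrix without having to name everything.
make_counts <- function(m, condition = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  sc_counts(m, condition)
}

# Isotropic Gaussian blobs in an 11-dimensional PC-like space.
make_blobs <- function(n_per, centers, dim = 11, sd = 1, seed = 0) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_along(centers), function(i) {
      m <- matrix(rnorm(n_per * dim, sd = sd), n_per, dim)
      m[, 1] <- m[, 1] + centers[[i]]
      m
    }))
    rownames(x) <- paste0("cell", seq_len(nrow(x)))
    x
  })
}

# Small simulation design used by unit tests (fast, 3 clusters).
small_design <- function(...) {
  args <- list(n_clusters = 3, cells_per_cluster = 80, n_genes = 500,
               n_regulons = 6, targets_per_regulon = 15,
               module_sizes = c(2, 2, 2), module_clusters = list(0, 1, 2),
               markers_per_cluster = 15)
  do.call(simulation_design, utils::modifyList(args, list(...)))
}
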