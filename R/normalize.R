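#' Log-normalize UMI counts
#'
#' Scales each cell to a common total and log-transforms:
#' `value(g,c) = ln(1 + count(g,c) * scale_factor / total(c))`. Zeros stay
#' zero, so sparsity is preserved.
#'
#' @param x An [sc_counts] object; every cell must have a positive total.
#' @param scale_factor Target total per cell (default 10,000).
#' @return Genes-by-cells matrix of normalized values (sparse if the input
#'   was sparse), with attribute `scale_factor`.
#' @export
log_normalize <- function(x, scale_factor = 10000) {
  stopifnot(inherits(x, "sc_counts"))
  m <- x$counts
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) {
    stop_validation("cells with zero total UMI present; run filter_cells first")
  }
  if (inherits(m, "Matrix")) {
    nm <- m %*% Matrix::Diagonal(x = scale_factor / tot)
    nm@x <- log1p(nm@x)
    dimnames(nm) <- dimnames(m)
  } else {
    nm <- log1p(sweep(m, 2, tot / scale_factor, "/"))
  }
  attr(nm, "scale_factor") <- scale_factor
  nm
}

#' Select highly variable genes by binned dispersion z-score
#'
#' Statistics are computed on back-transformed values `e^x - 1` of the
#' log-normalized matrix: per gene, `mu = ln(1 + mean)` and dispersion
#' `disp = ln(variance / mean)`. Genes are placed into `n_bins` equal-width
#' bins of `mu` and `disp` is z-scored within each bin. A gene is selected
#' when `x_low < mu < x_high` and `disp_z >= y_cutoff`.
#'
#' Genes with zero mean or zero variance have `disp = -Inf` and are never
#' selected. Bins with fewer than two genes, or zero dispersion spread, get
#' `disp_z = 0`.
#'
#' @param nm Log-normalized matrix from [log_normalize()] (>= 2 cells).
#' @param x_low,x_high Transformed-mean window.
#' @param y_cutoff Minimum within-bin dispersion z-score.
#' @param n_bins Number of equal-width mean bins.
#' @return Data frame with columns `gene`, `mu`, `disp`, `disp_z`, `selected`.
#' @export
find_variable_genes <- function(nm, x_low = 0.0125, x_high = 3, y_cutoff = 0.5,
                                n_bins = 20) {
  if (ncol(nm) < 2) stop_validation("variable-gene selection needs >= 2 cells")
  ex <- expm1(as_dense(nm))
  mu_raw <- rowMeans(ex)
  v <- apply(ex, 1, var)
  mu <- log1p(mu_raw)
  disp <- ifelse(mu_raw > 0 & v > 0, log(v / mu_raw), -Inf)

  disp_z <- rep(0, length(mu))
  finite <- is.finite(disp)
  if (any(finite)) {
    rng <- range(mu)
    if (diff(rng) == 0) {
      bins <- rep(1L, length(mu))
    } else {
      edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
      bins <- findInterval(mu, edges, rightmost.closed = TRUE, all.inside = TRUE)
    }
    for (b in unique(bins[finite])) {
      idx <- which(bins == b & finite)
      if (length(idx) < 2) next
      s <- sd(disp[idx])
      if (s == 0 || !is.finite(s)) next
      disp_z[idx] <- (disp[idx] - mean(disp[idx])) / s
    }
  }
  disp_z[!finite] <- -Inf
  selected <- mu > x_low & mu < x_high & disp_z >= y_cutoff & finite
  data.frame(gene = rownames(nm), mu = mu, disp = disp, disp_z = disp_z,
             selected = selected, stringsAsFactors = FALSE, row.names = NULL)
}

#' Regress out a per-cell covariate and scale
#'
#' For each gene, fits ordinary least squares of the normalized value on the
#' covariate (typically nUMI) plus an intercept, then centers the residuals,
#' scales them to unit variance, and clips to `[-clip, clip]`. Genes whose
#' residuals have zero variance yield an all-zero row.
#'
#' @param nm Log-normalized matrix (genes x cells).
#' @param covariate Numeric per-cell covariate, length `ncol(nm)`.
#' @param clip Symmetric clipping bound for scaled values.
#' @return Dense genes-by-cells matrix of scaled residuals.
#' @export
regress_and_scale <- function(nm, covariate, clip = 10) {
  m <- as_dense(nm)
  if (length(covariate) != ncol(m)) {
    stop_validation("covariate length must equal the number of cells")
  }
  u <- as.numeric(covariate)
  uc <- u - mean(u)
  ssu <- sum(uc^2)
  if (ssu == 0) {
    res <- m - rowMeans(m)
  } else {
    beta <- (m %*% uc) / ssu
    res <- m - rowMeans(m) - tcrossprod(as.numeric(beta), uc)
  }
  sds <- sqrt(rowSums(res^2) / (ncol(m) - 1L))
  zero <- sds < 1e-10 | !is.finite(sds)  # numerically exact fits count as constant
  sds[zero] <- 1
  out <- res / sds
  out[zero, ] <- 0
  out[out > clip] <- clip
  out[out < -clip] <- -clip
  dimnames(out) <- dimnames(m)
  out
}
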