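#' UMI count matrix container
#'
#' Bundles a genes-by-cells matrix of raw UMI counts with an optional
#' per-cell condition label (e.g. `"SPF"` / `"GF"`). All downstream
#' quality-control and normalization functions consume this container.
#'
#' @param counts Genes-by-cells matrix of nonnegative integer counts
#'   (base matrix or a `Matrix` sparse matrix) with unique row and column
#'   names identifying genes and cells.
#' @param condition Optional per-cell label, length `ncol(counts)`;
#'   coerced to factor.
#' @return An object of class `sc_counts`: a list with elements `counts`
#'   and `condition`.
#' @export
sc_counts <- function(counts, condition = NULL) {
  if (is.null(dim(counts)) || length(dim(counts)) != 2L) {
    stop_validation("counts must be a two-dimensional matrix")
  }
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop_validation("counts must carry gene (row) and cell (column) names")
  }
  if (anyDuplicated(rownames(counts))) stop_validation("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop_validation("duplicate cell ids")
  vals <- if (inherits(counts, "Matrix")) counts@x else counts
  if (length(vals) && (min(vals) < 0 || any(vals != floor(vals)))) {
    stop_validation("counts must be nonnegative integers")
  }
  if (!is.null(condition)) {
    if (length(condition) != ncol(counts)) {
      stop_validation("condition length must equal the number of cells")
    }
    condition <- factor(condition)
    names(condition) <- colnames(counts)
  }
  structure(list(counts = counts, condition = condition), class = "sc_counts")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("sc_counts: %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$condition)) {
    tab <- table(x$condition)
    cat("conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

#' Per-cell quality-control statistics
#'
#' Computes, for every cell, the number of genes detected (count > 0,
#' "nGene") and the total UMI count ("nUMI").
#'
#' @param x An [sc_counts] object.
#' @return A data.frame with columns `cell_id`, `n_genes`, `n_umi`.
#' @export
cell_qc_stats <- function(x) {
  stopifnot(inherits(x, "sc_counts"))
  m <- x$counts
  data.frame(
    cell_id = colnames(m),
    n_genes = as.integer(Matrix::colSums(m > 0)),
    n_umi   = as.numeric(Matrix::colSums(m)),
    stringsAsFactors = FALSE
  )
}

#' Filter cells by number of genes detected
#'
#' Removes cells with fewer than `min_genes` or more than `max_genes`
#' detected genes; cells exactly at either bound are retained. The gene
#' set is unchanged.
#'
#' @param x An [sc_counts] object.
#' @param min_genes,max_genes Inclusive bounds on genes detected per cell.
#' @param verbose Log retention counts.
#' @return Filtered [sc_counts].
#' @export
filter_cells <- function(x, min_genes = 200, max_genes = 2500, verbose = FALSE) {
  stopifnot(inherits(x, "sc_counts"))
  ng <- Matrix::colSums(x$counts > 0)
  keep <- ng >= min_genes & ng <= max_genes
  if (!any(keep)) warning("filter_cells: no cells pass the gene-count bounds")
  vlog(verbose, sprintf("filter_cells: %d/%d cells retained (%d <= nGene <= %d)",
                        sum(keep), length(keep), min_genes, max_genes))
  sc_counts(x$counts[, keep, drop = FALSE],
            if (is.null(x$condition)) NULL else x$condition[keep])
}

#' Filter genes by number of cells expressing them
#'
#' Retains genes detected (count > 0) in at least `min_cells` cells.
#'
#' @param x An [sc_counts] object.
#' @param min_cells Minimum number of cells in which a gene must be detected.
#' @param verbose Log retention counts.
#' @return Filtered [sc_counts].
#' @export
filter_genes <- function(x, min_cells = 3, verbose = FALSE) {
  stopifnot(inherits(x, "sc_counts"))
  nc <- Matrix::rowSums(x$counts > 0)
  keep <- nc >= min_cells
  vlog(verbose, sprintf("filter_genes: %d/%d genes retained (detected in >= %d cells)",
                        sum(keep), length(keep), min_cells))
  sc_counts(x$counts[keep, , drop = FALSE], x$condition)
}
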