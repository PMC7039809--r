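#' Read a UMI count matrix
#'
#' Reads raw counts from either a Matrix Market sparse triplet file with
#' `genes.tsv` / `barcodes.tsv` sidecars (the common droplet DGE layout) or
#' a dense tab-separated table whose first column holds gene ids and whose
#' header holds cell ids. Gene and cell order are preserved from the source.
#'
#' Deposited digital-gene-expression matrices come in both orientations;
#' `transpose = TRUE` accepts cells-as-rows input. Gene identifiers are
#' matched case-sensitively throughout the package (mouse gene symbols are
#' case-meaningful).
#'
#' @param path Path to the `.mtx` file or dense TSV.
#' @param format `"mtx"`, `"tsv"`, or `"auto"` (by file extension).
#' @param transpose If `TRUE`, the source stores cells as rows.
#' @param genes_path,barcodes_path Sidecar paths for `mtx` input; default
#'   `genes.tsv` and `barcodes.tsv` next to the matrix file.
#' @param condition Optional per-cell condition labels.
#' @param verbose Log dimensions read.
#' @return An [sc_counts] object.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "tsv"), transpose = FALSE,
                        genes_path = NULL, barcodes_path = NULL,
                        condition = NULL, verbose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    if (is.null(genes_path)) genes_path <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes_path)) barcodes_path <- file.path(dirname(path), "barcodes.tsv")
    if (!file.exists(genes_path)) stop_io("missing gene sidecar: ", genes_path)
    if (!file.exists(barcodes_path)) stop_io("missing barcode sidecar: ", barcodes_path)
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop_format("malformed MatrixMarket file: ",
                                                  conditionMessage(e)))
    genes <- read.delim(genes_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
    cells <- read.delim(barcodes_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
    if (transpose) m <- Matrix::t(m)
    if (nrow(m) != length(genes)) stop_format("gene sidecar length does not match matrix rows")
    if (ncol(m) != length(cells)) stop_format("barcode sidecar length does not match matrix columns")
    dimnames(m) <- list(genes, cells)
  } else {
    tab <- tryCatch(read.delim(path, header = TRUE, check.names = FALSE,
                               stringsAsFactors = FALSE),
                    error = function(e) stop_format("malformed TSV: ", conditionMessage(e)))
    if (ncol(tab) < 2) stop_format("dense TSV needs an id column plus at least one data column")
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop_format("non-numeric entries in dense TSV")
    rownames(m) <- ids
    if (transpose) m <- t(m)
  }
  vlog(verbose, sprintf("read_counts: %d genes x %d cells from %s", nrow(m), ncol(m), path))
  sc_counts(m, condition = condition)
}

#' Read regulons from a GMT file
#'
#' Each GMT line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Regulon
#' names conventionally follow `"TF(+)"`, and the gene set includes the TF
#' itself. Genes absent from an expression matrix supplied later are kept
#' here and intersected with the matrix universe at scoring time.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one per regulon).
#' @export
read_regulons <- function(path) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(list(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop_format("GMT line with fewer than 3 fields at line ", which(bad)[1])
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop_validation("duplicate regulon name: ", nm[duplicated(nm)][1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  small <- vapply(sets, length, 1L) < 2L
  if (any(small)) stop_validation("regulon with fewer than 2 genes: ", nm[small][1])
  stats::setNames(sets, nm)
}

#' Write regulons to a GMT file
#'
#' @param regulons Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(regulons, path) {
  lines <- vapply(seq_along(regulons), function(i) {
    paste(c(names(regulons)[i], "na", regulons[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table or matrix to CSV
#'
#' Data frames are written with a header in their (deterministic) native
#' order; matrices are written with row labels in a leading `row` column so
#' square matrices (e.g. CSI) round-trip with matching labels.
#'
#' @param obj A data.frame or matrix.
#' @param path Output path.
#' @export
write_table <- function(obj, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("directory does not exist: ", dir)
  if (is.matrix(obj) || inherits(obj, "Matrix")) {
    m <- as_dense(obj)
    df <- data.frame(row = rownames(m), as.data.frame(m, check.names = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE)
  } else {
    write.csv(as.data.frame(obj), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path CSV path.
#' @param as_matrix If `TRUE`, interpret a leading `row` column as row labels
#'   and return a numeric matrix.
#' @return A data.frame, or a matrix when `as_matrix = TRUE`.
#' @export
read_table <- function(path, as_matrix = FALSE) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (as_matrix) {
    if (names(df)[1] != "row") stop_format("matrix CSV must start with a 'row' column")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$row
    return(m)
  }
  df
}
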