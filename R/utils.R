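# Internal helpers shared across the pipeline.

#' @importFrom stats sd var cor prcomp rlnorm rnbinom rbinom runif hclust cutree as.dist wilcox.test p.adjust
#' @importFrom utils read.delim write.csv read.csv
#' @importFrom methods as
NULL

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("rscope_validation_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("rscope_format_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("rscope_io_error", "error")))
}

# Population (divide-by-n) z-score of a vector; constant vectors map to 0.
zscore_pop <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) return(rep(0, length(x)))
  (x - mu) / s
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0) {
    stop_validation("seed must be a single nonnegative integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

vlog <- function(verbose, ...) {
  if (isTRUE(verbose)) message("[rscope] ", ...)
}

# Coerce to a base dense matrix, keeping dimnames.
as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}
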