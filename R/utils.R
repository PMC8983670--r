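#' Log2 counts per million
#'
#' Library-size normalized log2-CPM with a pseudocount, the variance
#' stabilization used throughout the package before linear modelling.
#'
#' @param counts Non-negative matrix, genes (features) in rows, samples in
#'   columns.
#' @param prior_count Pseudocount added to every cell before the log (default
#'   0.5).
#' @return Matrix of the same dimensions with log2-CPM values.
#' @export
logcpm <- function(counts, prior_count = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample needs positive library size")
  log2(sweep(counts + prior_count, 2, lib + 2 * prior_count, "/") * 1e6)
}

# round-half-up to integer; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

# row-standardize a matrix (z-score each row across columns)
row_zscore <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  sdv[sdv == 0] <- 1
  (x - mu) / sdv
}

`%||%` <- function(a, b) if (is.null(a)) b else a
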