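#' Expected fraction of mRNA remaining under passive first-order decay
#'
#' With transcription of a gene shut off at time 0, first-order decay leaves
#' \eqn{2^{-t/t_{1/2}}} of the mature mRNA after \code{t} hours. The
#' expected passive downregulation in percent is
#' \code{100 * (1 - expected_remaining(t, t_half))}.
#'
#' @param t Elapsed time in hours (>= 0); vectorized.
#' @param t_half mRNA half-life in hours (> 0); vectorized.
#' @return Fraction remaining in (0, 1].
#' @examples
#' expected_remaining(0.75, 4.5)            # ~0.891
#' 100 * (1 - expected_remaining(0.75, 4.5)) # ~10.9% -> reported as 11%
#' @export
expected_remaining <- function(t, t_half) {
  if (any(t < 0)) stop("t must be >= 0")
  if (any(t_half <= 0)) stop("t_half must be positive")
  2^(-t / t_half)
}

#' Fold-change distributions stratified by mRNA half-life
#'
#' Joins a one-timepoint log2 fold-change profile with a half-life table,
#' bins genes by half-life (quantile bins by default, or fixed edges) and
#' summarizes the per-bin logFC distributions. Used to ask whether shorter
#' half-life genes are more strongly downregulated, the signature of passive
#' decay.
#'
#' @param fc Named numeric vector of log2 fold-changes (names = gene ids),
#'   or a data.frame with columns \code{gene_id} and \code{logfc}.
#' @param hl data.frame with columns \code{gene_id} and \code{t_half}
#'   (hours).
#' @param bins Either a single integer (number of quantile bins, default 4)
#'   or a numeric vector of fixed bin edges in hours.
#' @return A \code{decay_report} list: \code{per_bin} data.frame (bin label,
#'   n, median half-life, median logFC), \code{logfc_by_bin} (list of sorted
#'   per-bin logFC vectors, the cumulative distributions), and
#'   \code{n_unmatched} genes absent from the half-life table.
#' @export
fc_by_halflife <- function(fc, hl, bins = 4) {
  if (is.data.frame(fc)) fc <- stats::setNames(fc$logfc, fc$gene_id)
  if (any(hl$t_half <= 0)) stop("half-lives must be positive")
  idx <- match(names(fc), hl$gene_id)
  n_unmatched <- sum(is.na(idx))
  keep <- !is.na(idx)
  x <- fc[keep]
  th <- hl$t_half[idx[keep]]
  if (length(x) == 0) stop("no genes shared between fc and half-life table")
  if (length(bins) == 1) {
    edges <- stats::quantile(th, probs = seq(0, 1, length.out = bins + 1))
    edges[1] <- -Inf; edges[length(edges)] <- Inf
  } else {
    edges <- bins
  }
  bin <- cut(th, breaks = unique(edges), include.lowest = TRUE)
  if (nlevels(droplevels(bin)) < 2) stop("need >= 2 non-empty bins")
  per_bin <- do.call(rbind, lapply(levels(bin), function(l) {
    sel <- bin == l
    data.frame(bin = l, n = sum(sel),
               median_t_half = stats::median(th[sel]),
               median_logfc = stats::median(x[sel]), row.names = NULL)
  }))
  structure(list(per_bin = per_bin,
                 logfc_by_bin = lapply(levels(bin),
                                       function(l) sort(x[bin == l])),
                 n_unmatched = n_unmatched),
            class = "decay_report")
}

#' Consistency of observed downregulation with passive mRNA decay
#'
#' For a set of downregulated genes, compares the expected passive
#' downregulation at elapsed time \code{t} — computed from the genes'
#' median half-life under first-order decay — with the observed
#' downregulation, and declares the two consistent when they agree within
#' \code{tolerance} percentage points.
#'
#' The observed downregulation is, by default, the percent change implied by
#' the median logFC (\code{100 * (1 - 2^median(logfc))}); alternatively the
#' median of per-gene percent changes (\code{observed_method =
#' "median_pct"}).
#'
#' @param down_genes Character vector of downregulated gene ids.
#' @param fc Named numeric log2 fold-change vector (or data.frame, see
#'   \code{\link{fc_by_halflife}}).
#' @param hl Half-life table (\code{gene_id}, \code{t_half}).
#' @param t Elapsed time in hours.
#' @param tolerance Consistency tolerance in percentage points (default 5).
#' @param observed_method "pct_of_median_logfc" (default) or "median_pct".
#' @return List with \code{median_t_half}, \code{expected_pct},
#'   \code{observed_pct}, \code{consistent} and \code{n_genes}.
#' @export
decay_consistency <- function(down_genes, fc, hl, t, tolerance = 5,
                              observed_method = c("pct_of_median_logfc",
                                                  "median_pct")) {
  observed_method <- match.arg(observed_method)
  if (is.data.frame(fc)) fc <- stats::setNames(fc$logfc, fc$gene_id)
  down_genes <- intersect(down_genes, intersect(names(fc), hl$gene_id))
  if (length(down_genes) == 0) stop("empty set after joining on gene_id")
  th <- hl$t_half[match(down_genes, hl$gene_id)]
  lfc <- fc[down_genes]
  med_th <- stats::median(th)
  expected_pct <- 100 * (1 - expected_remaining(t, med_th))
  observed_pct <- switch(observed_method,
    pct_of_median_logfc = 100 * (1 - 2^stats::median(lfc)),
    median_pct = stats::median(100 * (1 - 2^lfc)))
  list(median_t_half = med_th,
       expected_pct = expected_pct,
       observed_pct = observed_pct,
       consistent = abs(expected_pct - observed_pct) <= tolerance,
       n_genes = length(down_genes))
}
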