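#' Simulate per-cell-type pseudo-bulk profiles with planted origins
#'
#' Each responsive gene responds only in its planted cell type(s), scaled by
#' the gene's \code{celltype_amplitude}; the nuclear (unprocessed) log2
#' fold-change at \code{timepoint} is taken from the gene's exact kinetics.
#' The bulk signal is the abundance-weighted mixture of the cell types'
#' true (noise-free) pseudo-bulk means, so the mixture identity holds
#' exactly before noise. Per-cell-type p-values come from two-sample t-tests
#' on log2 replicate values.
#'
#' @param celltypes data.frame with \code{celltype} and \code{abundance}
#'   (relative proportions; >= 2 rows).
#' @param genes List of \code{\link{gene_kinetics}}; responsive genes (those
#'   with \code{alpha_pulse != 1}) must carry a named
#'   \code{celltype_amplitude} vector with at least one nonzero entry.
#' @param timepoint Sampling time in hours (default 0.75).
#' @param n_replicates Replicates per condition per cell type (default 4).
#' @param noise_sd Log2-scale replicate noise SD (default 0.15).
#' @param expr_factor_sd SD of per-gene-per-type log-normal baseline
#'   expression factors (default 0.3).
#' @param seed RNG seed.
#' @return List: \code{pseudobulk_stress}, \code{pseudobulk_control} (noisy
#'   replicate-mean matrices, genes x cell types), \code{pvals},
#'   \code{true_stress}, \code{true_control} (noise-free means),
#'   \code{bulk_stress}, \code{bulk_control} (exact mixtures),
#'   \code{bulk_sign}, and \code{truth} (planted origin per gene).
#' @export
simulate_celltype_profiles <- function(celltypes, genes, timepoint = 0.75,
                                       n_replicates = 4, noise_sd = 0.15,
                                       expr_factor_sd = 0.3, seed = 1L) {
  if (nrow(celltypes) < 2) stop("need >= 2 cell types")
  set.seed(seed)
  cts <- as.character(celltypes$celltype)
  abund <- celltypes$abundance / sum(celltypes$abundance)
  ng <- length(genes)
  gid <- vapply(genes, function(g) g$gene_id, character(1))

  lfc <- numeric(ng)
  base <- numeric(ng)
  amp <- matrix(0, ng, length(cts), dimnames = list(gid, cts))
  for (i in seq_len(ng)) {
    g <- genes[[i]]
    tr <- simulate_kinetics(g, c(0, timepoint))
    base[i] <- tr$u[1]
    lfc[i] <- log2(tr$u[2] / tr$u[1])
    responsive <- g$alpha_pulse != 1
    a <- g$celltype_amplitude
    if (responsive && (is.null(a) || all(a == 0)))
      stop("gene ", g$gene_id,
           " is responsive but has all-zero celltype amplitudes")
    if (!is.null(a)) {
      unknown <- setdiff(names(a), cts)
      if (length(unknown))
        stop("unknown cell type(s) in amplitudes: ",
             paste(unknown, collapse = ", "))
      amp[i, names(a)] <- a
    }
  }

  f <- matrix(exp(stats::rnorm(ng * length(cts), 0, expr_factor_sd)),
              ng, length(cts))
  true_control <- base * f
  true_stress <- true_control * 2^(lfc * amp)
  dimnames(true_control) <- dimnames(true_stress) <- list(gid, cts)

  reps <- function(true_mean) {
    lapply(seq_len(n_replicates), function(r) {
      log2(true_mean) + matrix(stats::rnorm(length(true_mean), 0, noise_sd),
                               nrow = ng)
    })
  }
  rc <- reps(true_control)
  rs <- reps(true_stress)
  mean_lin <- function(rl) Reduce(`+`, lapply(rl, function(x) 2^x)) / length(rl)
  pseudobulk_control <- mean_lin(rc)
  pseudobulk_stress <- mean_lin(rs)
  dimnames(pseudobulk_control) <- dimnames(pseudobulk_stress) <-
    list(gid, cts)

  # vectorized equal-n two-sample t-test per gene x cell type (log2 scale)
  n <- n_replicates
  arr <- function(rl) array(unlist(rl), dim = c(ng, length(cts), n))
  ac <- arr(rc); as_ <- arr(rs)
  mdiff <- apply(as_, c(1, 2), mean) - apply(ac, c(1, 2), mean)
  vs <- apply(as_, c(1, 2), stats::var)
  vc <- apply(ac, c(1, 2), stats::var)
  tstat <- mdiff / sqrt((vs + vc) / n)
  pvals <- 2 * stats::pt(abs(tstat), df = 2 * n - 2, lower.tail = FALSE)
  dimnames(pvals) <- list(gid, cts)

  bulk_control <- as.vector(true_control %*% abund)
  bulk_stress <- as.vector(true_stress %*% abund)
  origin <- apply(amp, 1, function(a) {
    if (all(a == 0)) NA_character_ else paste(cts[a != 0], collapse = ",")
  })
  list(pseudobulk_stress = pseudobulk_stress,
       pseudobulk_control = pseudobulk_control,
       pvals = pvals,
       true_stress = true_stress, true_control = true_control,
       bulk_stress = stats::setNames(bulk_stress, gid),
       bulk_control = stats::setNames(bulk_control, gid),
       bulk_sign = sign(bulk_stress - bulk_control),
       truth = data.frame(gene_id = gid, logfc = lfc, origin = origin,
                          row.names = NULL),
       abundance = stats::setNames(abund, cts))
}
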