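#' Time-course design for the synthetic stress experiment
#'
#' Encodes the bulk RNA-seq study design the generator emulates: two
#' hippocampal regions sampled at five post-stress timepoints (45, 90, 120,
#' 180, 240 min) plus unstressed controls (timepoint 0).
#'
#' @param timepoints Strictly increasing positive times in hours after stress
#'   onset (default \code{c(0.75, 1.5, 2, 3, 4)}). Controls at time 0 are
#'   always added.
#' @param regions Region labels (default dHC and vHC).
#' @param n_replicates Biological replicates per region x timepoint group
#'   (>= 2, default 7).
#' @param library_size Expected total counts per sample (default 2e7).
#' @param nb_dispersion Negative-binomial dispersion; 0 gives Poisson noise.
#' @param seed RNG seed.
#' @return A \code{course_design} object.
#' @export
course_design <- function(timepoints = c(0.75, 1.5, 2, 3, 4),
                          regions = c("dHC", "vHC"),
                          n_replicates = 7,
                          library_size = 2e7,
                          nb_dispersion = 0.05,
                          seed = 1L) {
  if (any(timepoints <= 0) || is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be positive and strictly increasing")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (length(regions) < 1) stop("at least one region required")
  structure(list(timepoints = timepoints, regions = regions,
                 n_replicates = n_replicates, library_size = library_size,
                 nb_dispersion = nb_dispersion, seed = as.integer(seed)),
            class = "course_design")
}

#' Build a panel of gene kinetics with planted stress responses
#'
#' Convenience generator for a heterogeneous gene panel: half-lives are drawn
#' log-normal (median \code{half_life_median}, sigma on the natural-log
#' scale), a subset of genes receives a transcriptional induction pulse, and
#' a subset undergoes transcriptional shutdown/rerouting
#' (\code{alpha -> alpha * (1 - rerouting)}).
#'
#' @param n_genes Total number of genes.
#' @param n_induced Number of pulse-induced genes.
#' @param n_shutdown Number of genes with reduced transcription after onset.
#' @param induced_fold Induction factor for induced genes.
#' @param rerouting Fraction of transcription lost by shutdown genes
#'   (1 = complete shutdown).
#' @param pulse_start,pulse_end Induction window in hours.
#' @param half_life_median Median mRNA half-life in hours (default 4.5).
#' @param half_life_sigma SD of log(half-life) (default 0.8).
#' @param beta Processing rate, 1/hour (default 20, pre-mRNA half-life
#'   about 2 minutes).
#' @param seed RNG seed.
#' @return List of \code{\link{gene_kinetics}} objects. Induced genes are
#'   first, then shutdown genes, then unresponsive genes; each carries a
#'   \code{response} attribute ("induced", "shutdown" or "none").
#' @export
make_kinetics_panel <- function(n_genes = 1000, n_induced = 50,
                                n_shutdown = 50, induced_fold = 6,
                                rerouting = 1, pulse_start = 0,
                                pulse_end = 0.75, half_life_median = 4.5,
                                half_life_sigma = 0.8, beta = 20,
                                seed = 1L) {
  if (n_induced + n_shutdown > n_genes)
    stop("n_induced + n_shutdown exceeds n_genes")
  set.seed(seed)
  hl <- exp(rnorm(n_genes, log(half_life_median), half_life_sigma))
  a0 <- exp(rnorm(n_genes, log(10), 1))
  resp <- rep("none", n_genes)
  if (n_induced > 0) resp[seq_len(n_induced)] <- "induced"
  if (n_shutdown > 0) resp[n_induced + seq_len(n_shutdown)] <- "shutdown"
  lapply(seq_len(n_genes), function(i) {
    pulse <- switch(resp[i],
                    induced = induced_fold,
                    shutdown = 1 - rerouting,
                    none = 1)
    # alpha_pulse = 0 is valid (shutdown); guard tiny negatives
    pulse <- max(pulse, 0)
    g <- gene_kinetics(sprintf("g%04d", i), alpha_baseline = a0[i],
                       alpha_pulse = pulse, pulse_start = pulse_start,
                       pulse_end = if (resp[i] == "shutdown") Inf else pulse_end,
                       beta = beta, half_life = hl[i])
    attr(g, "response") <- resp[i]
    g
  })
}

#' Simulate bulk RNA-seq count matrices for processed and unprocessed
#' transcripts
#'
#' Evaluates each gene's exact kinetics at the design timepoints, scales
#' abundances to the expected library size (a single scale factor per
#' fraction, anchored at the pre-stress steady state) and draws
#' negative-binomial counts. Controls are the timepoint-0 samples.
#'
#' @param design A \code{\link{course_design}}.
#' @param genes List of \code{\link{gene_kinetics}} objects.
#' @return A list with \code{processed} and \code{unprocessed} count
#'   matrices (genes x samples), \code{samples} metadata (region, timepoint,
#'   replicate), and a \code{truth} data.frame of per-gene true log2
#'   fold-changes (vs. time 0) per timepoint for both fractions.
#' @export
simulate_bulk_counts <- function(design, genes) {
  stopifnot(inherits(design, "course_design"))
  if (length(genes) < 1) stop("at least one gene required")
  set.seed(design$seed)

  tps <- c(0, design$timepoints)
  gid <- vapply(genes, function(g) g$gene_id, character(1))
  traj <- lapply(genes, simulate_kinetics, times = tps)
  u_mat <- do.call(rbind, lapply(traj, function(d) d$u))
  s_mat <- do.call(rbind, lapply(traj, function(d) d$s))
  rownames(u_mat) <- rownames(s_mat) <- gid

  # fixed per-fraction scale anchored at baseline so composition shifts do
  # not bias fold-changes
  ks <- design$library_size / sum(s_mat[, 1])
  ku <- design$library_size / sum(u_mat[, 1])

  samples <- expand.grid(replicate = seq_len(design$n_replicates),
                         timepoint = tps, region = design$regions,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("region", "timepoint", "replicate")]
  samples$sample <- sprintf("%s_t%g_r%d", samples$region,
                            samples$timepoint, samples$replicate)

  draw <- function(mu_mat, scale) {
    mu <- mu_mat[, match(samples$timepoint, tps), drop = FALSE] * scale
    n <- length(mu)
    cnt <- if (design$nb_dispersion == 0) {
      rpois(n, lambda = mu)
    } else {
      rnbinom(n, mu = mu, size = 1 / design$nb_dispersion)
    }
    m <- matrix(cnt, nrow = nrow(mu_mat),
                dimnames = list(gid, samples$sample))
    m
  }
  processed <- draw(s_mat, ks)
  unprocessed <- draw(u_mat, ku)

  truth <- do.call(rbind, lapply(seq_along(design$timepoints), function(j) {
    data.frame(gene_id = gid, timepoint = design$timepoints[j],
               logfc_processed = log2(s_mat[, j + 1] / s_mat[, 1]),
               logfc_unprocessed = log2(u_mat[, j + 1] / u_mat[, 1]),
               row.names = NULL)
  }))
  list(processed = processed, unprocessed = unprocessed,
       samples = samples, truth = truth)
}
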