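#' Specification for the synthetic phosphoproteomic experiment
#'
#' Parameters of the simulated peptide-intensity matrix: a transient
#' phosphorylation wave peaking minutes after stress onset and essentially
#' gone by 30 minutes, measured on log2-scale intensities with left-censored
#' missingness.
#'
#' @param n_peptides Number of modified peptides.
#' @param phospho_fraction Fraction of peptides carrying a phospho flag
#'   (default 0.62).
#' @param responsive_fraction Fraction of peptides that respond to stress
#'   (default 0.05); responsive peptides are enriched for the phospho flag.
#' @param wave_peak_time Time of the phosphorylation-wave peak in hours
#'   (default 0.1, i.e. immediately after the 6-minute stressor).
#' @param wave_decay_time Time after onset at which the wave has decayed to
#'   1 percent of its peak (hours, default 0.5).
#' @param effect_sd SD of responsive peptides' peak log2 effects (default 1);
#'   0 yields a global null.
#' @param missing_rate Overall fraction of missing cells (default 0.2).
#' @param censoring_strength Steepness of the left-censoring logistic in
#'   1/log2-intensity units; 0 gives missingness completely at random.
#' @param seed RNG seed.
#' @return A \code{phospho_sim_spec} object.
#' @export
phospho_sim_spec <- function(n_peptides = 2000, phospho_fraction = 0.62,
                             responsive_fraction = 0.05,
                             wave_peak_time = 0.1, wave_decay_time = 0.5,
                             effect_sd = 1, missing_rate = 0.2,
                             censoring_strength = 1.5, seed = 1L) {
  if (phospho_fraction < 0 || phospho_fraction > 1)
    stop("phospho_fraction must be in [0,1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0,1)")
  if (wave_peak_time <= 0 || wave_decay_time <= wave_peak_time)
    stop("need 0 < wave_peak_time < wave_decay_time")
  structure(list(n_peptides = n_peptides,
                 phospho_fraction = phospho_fraction,
                 responsive_fraction = responsive_fraction,
                 wave_peak_time = wave_peak_time,
                 wave_decay_time = wave_decay_time,
                 effect_sd = effect_sd, missing_rate = missing_rate,
                 censoring_strength = censoring_strength,
                 seed = as.integer(seed)),
            class = "phospho_sim_spec")
}

# log-normal wave shape: 1 at the peak, ~0 at t = 0, and 1% of peak at
# t = wave_decay_time
.phospho_wave <- function(t, peak, decay99) {
  sigma <- log(decay99 / peak) / sqrt(2 * log(100))
  ifelse(t <= 0, 0, exp(-(log(t / peak))^2 / (2 * sigma^2)))
}

#' Simulate a phosphoproteomic peptide-intensity matrix
#'
#' Generates log2 intensities for unstressed controls and stressed groups
#' collected at the given timepoints. Responsive peptides carry a log2
#' effect following a transient wave (peak at \code{wave_peak_time},
#' negligible by \code{wave_decay_time}); missingness is left-censored so
#' low-intensity measurements are preferentially lost.
#'
#' @param spec A \code{\link{phospho_sim_spec}}.
#' @param timepoints Stressed-group collection times in hours (default
#'   \code{c(0.1, 0.25, 0.5, 0.75)}, i.e. 6, 15, 30, 45 min).
#' @param n_per_group Samples per group, controls included (default 6).
#' @param baseline_mean,baseline_sd Mean/SD of peptide baseline log2
#'   intensities.
#' @param noise_sd Residual measurement SD on the log2 scale.
#' @return List: \code{matrix} (with \code{NA}s), \code{complete} (the same
#'   matrix before censoring), \code{samples} (condition, timepoint),
#'   \code{peptides} (is_phospho, responsive, peak amplitude).
#' @export
simulate_phospho <- function(spec, timepoints = c(0.1, 0.25, 0.5, 0.75),
                             n_per_group = 6, baseline_mean = 20,
                             baseline_sd = 2, noise_sd = 0.35) {
  stopifnot(inherits(spec, "phospho_sim_spec"))
  set.seed(spec$seed)
  np <- spec$n_peptides
  conds <- c("control", sprintf("t%g", timepoints))
  tvec <- c(0, timepoints)
  samples <- data.frame(
    sample = sprintf("%s_r%d", rep(conds, each = n_per_group),
                     rep(seq_len(n_per_group), length(conds))),
    condition = rep(conds, each = n_per_group),
    timepoint = rep(tvec, each = n_per_group))

  n_resp <- round(spec$responsive_fraction * np)
  responsive <- c(rep(TRUE, n_resp), rep(FALSE, np - n_resp))
  # phospho flag: responsive peptides enriched (logit shift +1.5)
  base_logit <- stats::qlogis(min(max(spec$phospho_fraction, 1e-6), 1 - 1e-6))
  p_flag <- stats::plogis(base_logit + ifelse(responsive, 1.5, 0))
  # keep the overall fraction close to spec by compensating non-responsive
  if (np > n_resp) {
    target <- spec$phospho_fraction * np - sum(p_flag[responsive])
    p_nr <- min(max(target / (np - n_resp), 0), 1)
    p_flag[!responsive] <- p_nr
  }
  is_phospho <- stats::runif(np) < p_flag

  amp <- numeric(np)
  amp[responsive] <- stats::rnorm(n_resp, 0, spec$effect_sd)
  baseline <- stats::rnorm(np, baseline_mean, baseline_sd)

  wave <- .phospho_wave(samples$timepoint, spec$wave_peak_time,
                        spec$wave_decay_time)
  mu <- outer(baseline, rep(1, nrow(samples))) +
    outer(amp, wave)
  complete <- mu + matrix(stats::rnorm(length(mu), 0, noise_sd),
                          nrow = np)
  rownames(complete) <- sprintf("pep%05d", seq_len(np))
  colnames(complete) <- samples$sample

  m <- complete
  if (spec$missing_rate > 0) {
    x <- as.vector(complete)
    if (spec$censoring_strength == 0) {
      pm <- rep(spec$missing_rate, length(x))
    } else {
      cs <- spec$censoring_strength
      f <- function(thr) mean(stats::plogis(cs * (thr - x))) - spec$missing_rate
      thr <- stats::uniroot(f, range(x) + c(-20, 20))$root
      pm <- stats::plogis(cs * (thr - x))
    }
    m[matrix(stats::runif(length(x)) < pm, nrow = np)] <- NA
  }
  list(matrix = m, complete = complete, samples = samples,
       peptides = data.frame(peptide = rownames(complete),
                             is_phospho = is_phospho,
                             responsive = responsive,
                             amplitude = amp, row.names = NULL))
}
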