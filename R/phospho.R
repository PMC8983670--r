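#' Missing-value filter for peptide intensity matrices
#'
#' Keeps a peptide if, in at least one condition, the number of missing
#' values does not exceed \code{thr} — i.e. the peptide is reasonably
#' complete somewhere, so a condition-wise comparison is possible after
#' imputation.
#'
#' @param m Peptides x samples matrix of log2 intensities with \code{NA} for
#'   missing values.
#' @param condition Factor/character of length \code{ncol(m)} giving each
#'   sample's condition (>= 2 conditions).
#' @param thr Maximum number of missing values tolerated within the best
#'   condition (default 2).
#' @return The filtered matrix, with attribute \code{"filter_report"} giving
#'   kept/dropped counts.
#' @export
filter_missing <- function(m, condition, thr = 2) {
  if (thr < 0) stop("thr must be >= 0")
  condition <- as.factor(condition)
  if (nlevels(condition) < 2) stop("need >= 2 conditions")
  if (length(condition) != ncol(m)) stop("condition length must match columns")
  miss <- is.na(m)
  per_cond <- vapply(levels(condition), function(l) {
    rowSums(miss[, condition == l, drop = FALSE])
  }, numeric(nrow(m)))
  keep <- apply(per_cond, 1, min) <= thr
  out <- m[keep, , drop = FALSE]
  attr(out, "filter_report") <- c(kept = sum(keep), dropped = sum(!keep))
  message(sum(!keep), " peptide(s) dropped by the missing-value filter")
  out
}

#' Left-censored missing-value imputation (MinProb)
#'
#' Imputes each missing cell with a draw from a normal distribution centred
#' at that sample's \code{q}-quantile of observed log2 intensities — i.e.
#' near the detection floor, reflecting that missingness in label-free
#' proteomics is predominantly left-censored. The spread is
#' \code{sigma_scale} times the median of the per-sample observed standard
#' deviations.
#'
#' @param m Peptides x samples log2-intensity matrix with \code{NA}s.
#' @param q Quantile of the observed distribution used as the imputation
#'   centre (default 0.01).
#' @param sigma_scale Multiplier on the spread (default 1).
#' @param seed RNG seed; identical seeds give identical imputations.
#' @return Complete matrix of the same dimensions.
#' @export
impute_minprob <- function(m, q = 0.01, sigma_scale = 1.0, seed = 1L) {
  obs_per_sample <- colSums(!is.na(m))
  if (any(obs_per_sample == 0))
    stop("sample(s) with zero observed values: ",
         paste(colnames(m)[obs_per_sample == 0], collapse = ", "))
  if (!anyNA(m)) return(m)
  set.seed(seed)
  centers <- apply(m, 2, function(x) stats::quantile(x, q, na.rm = TRUE))
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  sigma <- sigma_scale * stats::median(sds, na.rm = TRUE)
  out <- m
  for (j in seq_len(ncol(m))) {
    miss <- which(is.na(m[, j]))
    if (length(miss))
      out[miss, j] <- stats::rnorm(length(miss), centers[j], sigma)
  }
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment of raw p-values, capped at 1 and monotone in rank.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values (FDR) of the same length.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Moderated two-group differential test
#'
#' Empirical-Bayes moderated t-test: per-peptide residual variances are
#' shrunken toward a pooled prior (d0, s0^2) estimated by moment matching on
#' the variance distribution, and the t statistic is referred to a t
#' distribution with df + d0 degrees of freedom. An optional blocking factor
#' is absorbed as additive covariates.
#'
#' @param m Complete peptides x samples matrix (log2 intensities).
#' @param groups Factor/character of sample groups.
#' @param contrast Character vector of two group levels; the reported
#'   \code{log2fc} is \code{mean(contrast[1]) - mean(contrast[2])}.
#' @param blocks Optional blocking factor.
#' @param moderate Set \code{FALSE} (or prior df 0) to recover the ordinary
#'   two-sample t-test.
#' @return data.frame with \code{feature, log2fc, t, p_value, fdr} and
#'   attribute \code{"prior"} (estimated d0 and s0^2).
#' @export
moderated_diff <- function(m, groups, contrast, blocks = NULL,
                           moderate = TRUE) {
  groups <- as.character(groups)
  if (length(contrast) != 2 || !all(contrast %in% groups))
    stop("contrast must name two groups present in `groups`")
  sel <- groups %in% contrast
  Y <- as.matrix(m)[, sel, drop = FALSE]
  g <- factor(groups[sel], levels = contrast)
  if (any(table(g) < 2)) stop("need >= 2 samples per group")
  X <- stats::model.matrix(~g)
  if (!is.null(blocks)) {
    b <- factor(blocks[sel])
    if (nlevels(b) > 1) X <- stats::model.matrix(~g + b)
  }
  fit <- .ols_rows(Y, X)
  if (fit$df < 1) stop("zero residual degrees of freedom")
  s2 <- fit$rss / fit$df
  # coefficient 2 is contrast[2] - contrast[1]
  lfc <- -fit$coef[, 2]
  cvar <- fit$xtx_inv[2, 2]
  if (moderate) {
    sq <- .squeeze_var(s2, fit$df)
    tval <- lfc / sqrt(sq$var_post * cvar)
    dfree <- fit$df + sq$df_prior
    prior <- c(df_prior = sq$df_prior, var_prior = sq$var_prior)
  } else {
    tval <- lfc / sqrt(s2 * cvar)
    dfree <- fit$df
    prior <- c(df_prior = 0, var_prior = NA_real_)
  }
  p <- 2 * stats::pt(abs(tval), df = dfree, lower.tail = FALSE)
  out <- data.frame(feature = rownames(m) %||% seq_len(nrow(m)),
                    log2fc = lfc, t = tval, p_value = p, fdr = bh_fdr(p),
                    row.names = NULL)
  attr(out, "prior") <- prior
  out
}

#' Phosphopeptide enrichment among significant peptides
#'
#' Fraction of significant peptides that are phosphopeptides (integer
#' percent, round-half-up), plus the odds ratio and two-sided Fisher exact
#' p-value of the 2x2 phospho x significant table.
#'
#' @param is_phospho Logical vector, one per peptide.
#' @param significant Logical vector, one per peptide.
#' @return List with \code{fraction_phospho_sig} (percent),
#'   \code{odds_ratio}, \code{fisher_p} and the 2x2 \code{table}.
#' @export
enrichment_stats <- function(is_phospho, significant) {
  stopifnot(length(is_phospho) == length(significant))
  n_sig <- sum(significant)
  tab <- table(factor(is_phospho, levels = c(TRUE, FALSE)),
               factor(significant, levels = c(TRUE, FALSE)),
               dnn = c("phospho", "significant"))
  if (n_sig == 0) {
    warning("no significant peptides; enrichment fraction undefined")
    frac <- NA_real_
  } else {
    frac <- round_half_up(100 * sum(is_phospho & significant) / n_sig)
  }
  ft <- stats::fisher.test(tab)
  list(fraction_phospho_sig = frac,
       odds_ratio = unname(ft$estimate),
       fisher_p = ft$p.value,
       table = tab)
}

#' Per-peptide two-way ANOVA with interaction (e.g. stress x sex)
#'
#' Ordinary least-squares two-way ANOVA fitted to every peptide at once;
#' reports interaction and main-effect p-values. All four factor cells must
#' be populated.
#'
#' @param m Complete peptides x samples matrix.
#' @param f1,f2 Two-level factors of length \code{ncol(m)}.
#' @return data.frame with \code{feature, p_f1, p_f2, p_interaction} and the
#'   interaction coefficient \code{coef_interaction}.
#' @export
interaction_anova <- function(m, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  if (nlevels(f1) != 2 || nlevels(f2) != 2)
    stop("both factors must have exactly two levels")
  if (any(table(f1, f2) == 0)) stop("empty factor cell")
  Y <- as.matrix(m)
  X <- stats::model.matrix(~f1 * f2)
  ft_int <- .drop_ftest(Y, X, drop = 4, moderate = FALSE)
  ft_f1 <- .drop_ftest(Y, X[, -4], drop = 2, moderate = FALSE)
  ft_f2 <- .drop_ftest(Y, X[, -4], drop = 3, moderate = FALSE)
  data.frame(feature = rownames(m) %||% seq_len(nrow(m)),
             p_f1 = ft_f1$p, p_f2 = ft_f2$p,
             p_interaction = ft_int$p,
             coef_interaction = ft_int$coef[, 4],
             row.names = NULL)
}
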