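#' Build confidence-weighted regulons from a raw interaction table
#'
#' Attaches per-category confidence weights to TF-target interactions,
#' discards category E (lowest confidence), and drops TFs with fewer than
#' \code{min_targets} remaining targets.
#'
#' @param raw data.frame with columns \code{tf}, \code{target},
#'   \code{category} (one of A..E) and \code{mode} (+1 activation, -1
#'   repression).
#' @param category_weights Named numeric weights per category (default
#'   A 1.0, B 0.8, C 0.6, D 0.4; only the ordering matters downstream).
#' @param min_targets Minimum targets per retained TF (default 5).
#' @return data.frame of class \code{regulon_set} with \code{tf, target,
#'   weight, mode}.
#' @export
build_regulons <- function(raw,
                           category_weights = c(A = 1.0, B = 0.8,
                                                C = 0.6, D = 0.4),
                           min_targets = 5) {
  if (!all(raw$category %in% c("A", "B", "C", "D", "E")))
    stop("unknown regulon category")
  if (!all(raw$mode %in% c(-1, 1))) stop("mode must be +1 or -1")
  keep <- raw$category != "E"
  out <- data.frame(tf = raw$tf[keep], target = raw$target[keep],
                    weight = unname(category_weights[raw$category[keep]]),
                    mode = raw$mode[keep], row.names = NULL)
  if (any(out$weight <= 0) || anyNA(out$weight))
    stop("category weights must be positive for categories A-D")
  sizes <- table(out$tf)
  small <- names(sizes)[sizes < min_targets]
  dropped_e <- setdiff(unique(raw$tf), unique(out$tf))
  if (length(small) || length(dropped_e))
    message(length(small) + length(dropped_e),
            " TF(s) dropped (category-E only or < ", min_targets, " targets)")
  out <- out[!out$tf %in% small, , drop = FALSE]
  class(out) <- c("regulon_set", "data.frame")
  out
}

#' Sample-wise TF activity from weighted regulons
#'
#' Scores each TF in each sample as the confidence- and sign-weighted mean of
#' its targets' expression z-scores:
#' \deqn{A(tf, j) = \sum_i w_i m_i z_{ij} / \sum_i w_i}
#' Expression is row-standardized internally (idempotent on already
#' standardized input). Pleiotropic targets — genes belonging to more than
#' \code{p_max} regulons — are down-weighted by the number of regulons they
#' belong to.
#'
#' @param expr Genes x samples expression matrix (typically unprocessed
#'   log-CPM).
#' @param regulons A \code{\link{build_regulons}} table.
#' @param min_targets TFs with fewer expressed targets are dropped.
#' @param p_max Pleiotropy threshold (default 10).
#' @return TF x sample activity matrix.
#' @export
score_activity <- function(expr, regulons, min_targets = 5, p_max = 10) {
  expr <- as.matrix(expr)
  z <- row_zscore(expr)
  reg <- regulons[regulons$target %in% rownames(z), , drop = FALSE]
  if (nrow(reg) == 0) stop("no regulon targets present in the expression matrix")
  n_reg <- as.numeric(table(reg$target)[reg$target])
  w <- as.numeric(reg$weight / ifelse(n_reg > p_max, n_reg, 1))
  sizes <- table(reg$tf)
  keep_tf <- names(sizes)[sizes >= min_targets]
  if (length(keep_tf) < length(sizes))
    message(length(sizes) - length(keep_tf),
            " TF(s) dropped: < ", min_targets, " targets in expression matrix")
  if (length(keep_tf) == 0) stop("no TF retains enough expressed targets")
  act <- vapply(keep_tf, function(tf) {
    sel <- reg$tf == tf
    ww <- w[sel] * reg$mode[sel]
    colSums(z[reg$target[sel], , drop = FALSE] * ww) / sum(abs(ww))
  }, numeric(ncol(z)))
  t(act)
}

#' Differential TF activity over the time course
#'
#' Fits per-TF linear models \code{activity ~ region + timepoint} and tests
#' dropping the timepoint terms with a variance-moderated F-test. A TF is
#' called differentially active when it passes all three filters: FDR below
#' \code{fdr_thr}, maximum absolute activity change across timepoints above
#' \code{lfc_thr}, and mean log-CPM of the TF's own transcript at least
#' \code{logcpm_thr} (activity scores are log-scale-like, so their group-mean
#' difference plays the role of a log-fold change).
#'
#' @param act TF x sample activity matrix.
#' @param design data.frame with per-sample \code{region} and
#'   \code{timepoint} (timepoint 0 = control).
#' @param tf_logcpm Optional named vector of mean log-CPM of each TF's own
#'   transcript; TFs below \code{logcpm_thr} (or absent) fail the expression
#'   filter. If \code{NULL} the filter is skipped with a message.
#' @param fdr_thr,lfc_thr,logcpm_thr The three thresholds (defaults 0.005,
#'   0.2, 2).
#' @return data.frame per TF: \code{tf, f, p_value, fdr, max_abs_change,
#'   logcpm, passed}.
#' @export
differential_activity <- function(act, design, tf_logcpm = NULL,
                                  fdr_thr = 0.005, lfc_thr = 0.2,
                                  logcpm_thr = 2) {
  tp <- factor(design$timepoint)
  if (nlevels(tp) < 2) stop("need >= 2 timepoints")
  region <- factor(design$region)
  X <- if (nlevels(region) > 1) stats::model.matrix(~region + tp)
       else stats::model.matrix(~tp)
  drop_cols <- grep("^tp", colnames(X))
  ft <- .drop_ftest(as.matrix(act), X, drop = drop_cols, moderate = TRUE)
  max_change <- apply(abs(ft$coef[, drop_cols, drop = FALSE]), 1, max)
  fdr <- bh_fdr(ft$p)
  if (is.null(tf_logcpm)) {
    message("no tf_logcpm supplied; expression filter skipped")
    lcpm <- rep(Inf, nrow(act))
  } else {
    lcpm <- tf_logcpm[rownames(act)]
    lcpm[is.na(lcpm)] <- -Inf
  }
  data.frame(tf = rownames(act), f = ft$f, p_value = ft$p, fdr = fdr,
             max_abs_change = max_change, logcpm = unname(lcpm),
             passed = fdr < fdr_thr & max_change > lfc_thr &
               lcpm >= logcpm_thr,
             row.names = NULL)
}

#' Merged TF-target / temporal-logFC matrix
#'
#' Builds the gene x TF matrix with entries weight x mode, z-scored per TF
#' column over its nonzero support (genes outside the regulon stay exactly
#' 0, preserving sparsity; documented convention), and concatenates the
#' genes' log2 fold-change columns.
#'
#' @param regulons A \code{\link{build_regulons}} table.
#' @param logfc Genes x columns matrix of log2 fold-changes (e.g. 45/90/120
#'   min, unprocessed and processed); rownames are gene ids.
#' @return Numeric matrix, genes x (TFs + logFC columns).
#' @export
tf_target_matrix <- function(regulons, logfc) {
  genes <- rownames(logfc)
  tfs <- sort(unique(regulons$tf))
  tm <- matrix(0, nrow = length(genes), ncol = length(tfs),
               dimnames = list(genes, tfs))
  sel <- regulons$target %in% genes
  tm[cbind(match(regulons$target[sel], genes),
           match(regulons$tf[sel], tfs))] <-
    regulons$weight[sel] * regulons$mode[sel]
  for (j in seq_len(ncol(tm))) {
    nz <- tm[, j] != 0
    if (sum(nz) > 1 && stats::sd(tm[nz, j]) > 0) {
      tm[nz, j] <- (tm[nz, j] - mean(tm[nz, j])) / stats::sd(tm[nz, j])
    }
  }
  cbind(tm, as.matrix(logfc))
}

#' Co-cluster genes on regulon membership and temporal profile
#'
#' Partitioning around medoids (PAM, Euclidean dissimilarity) on the merged
#' TF-target / logFC matrix. PAM's build-step initialization makes the
#' result deterministic.
#'
#' @param tm Merged matrix from \code{\link{tf_target_matrix}} (or any
#'   numeric gene x feature matrix).
#' @param k Number of clusters (default 9).
#' @return List with \code{assignment} (named integer vector),
#'   \code{sizes}, and \code{medoids} (gene ids of cluster medoids).
#' @export
cocluster <- function(tm, k = 9) {
  n <- nrow(tm)
  if (k < 2 || k > n) stop("k must be in [2, n]")
  if (k == n) {
    asg <- stats::setNames(seq_len(n), rownames(tm))
    return(list(assignment = asg, sizes = rep(1L, n),
                medoids = rownames(tm)))
  }
  fit <- cluster::pam(tm, k = k, metric = "euclidean")
  list(assignment = fit$clustering,
       sizes = as.integer(table(fit$clustering)),
       medoids = rownames(tm)[fit$id.med])
}
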