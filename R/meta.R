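#' K-means clustering of temporal logFC profiles
#'
#' Euclidean k-means with multiple random restarts (best inertia kept) on a
#' feature x (region, timepoint) logFC matrix. Clusters are relabeled by
#' decreasing size; clusters smaller than \code{min_size} are excluded from
#' the report but listed, never silently dropped.
#'
#' @param m Numeric matrix, features in rows (no missing values).
#' @param k Number of centers (>= 2). The choice of k is deliberately a user
#'   input (see \code{\link{elbow_report}}).
#' @param min_size Minimum reported cluster size (default 15).
#' @param seed RNG seed.
#' @param n_init Number of random restarts (default 50).
#' @return A \code{cluster_result} list: \code{assignment} (named, labels
#'   ordered by decreasing cluster size), \code{sizes}, \code{included},
#'   \code{excluded}, \code{summary} (per cluster: per-column mean, SEM,
#'   SD), \code{tot_withinss}.
#' @export
kmeans_profiles <- function(m, k, min_size = 15, seed = 1L, n_init = 50) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("profile matrix must be complete")
  if (k < 2) stop("k must be >= 2")
  if (nrow(m) < k) stop("need at least k features")
  set.seed(seed)
  n_distinct <- nrow(unique(m))
  if (n_distinct < k) {
    # degenerate input: fewer distinct profiles than centers
    key <- apply(m, 1, paste, collapse = "\r")
    cl <- as.integer(factor(key, levels = unique(key)))
    tot_withinss <- 0
  } else {
    km <- stats::kmeans(m, centers = k, nstart = n_init, iter.max = 100)
    cl <- km$cluster
    tot_withinss <- km$tot.withinss
  }
  sizes <- table(cl)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- match(cl, as.integer(names(sizes))[ord])
  names(relabel) <- rownames(m)
  sizes <- as.integer(sort(sizes, decreasing = TRUE))
  labs <- seq_along(sizes)
  included <- labs[sizes >= min_size]
  excluded <- labs[sizes < min_size]
  summ <- lapply(labs, function(l) {
    sub <- m[relabel == l, , drop = FALSE]
    data.frame(column = colnames(m) %||% seq_len(ncol(m)),
               mean = colMeans(sub),
               sem = apply(sub, 2, stats::sd) / sqrt(nrow(sub)),
               sd = apply(sub, 2, stats::sd), row.names = NULL)
  })
  structure(list(assignment = relabel, sizes = sizes, included = included,
                 excluded = excluded, summary = summ,
                 tot_withinss = tot_withinss, k = k, min_size = min_size),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k=%d, %d feature(s); sizes: %s\n", x$k,
              length(x$assignment), paste(x$sizes, collapse = ", ")))
  if (length(x$excluded))
    cat("excluded (<", x$min_size, "features):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Inertia and silhouette diagnostics over a range of k
#'
#' Selection aid only: reports within-cluster inertia and mean silhouette
#' width for each candidate k. Never auto-selects k — different rating
#' methods rarely agree, so the choice is left to inspection.
#'
#' @param m Feature x column numeric matrix (>= 3 rows).
#' @param k_range Candidate numbers of centers, within [2, nrow - 1].
#' @param seed,n_init Passed to \code{\link[stats]{kmeans}}.
#' @return data.frame with \code{k, inertia, mean_silhouette}.
#' @export
elbow_report <- function(m, k_range, seed = 1L, n_init = 20) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("need >= 3 features for diagnostics")
  if (any(k_range < 2 | k_range > nrow(m) - 1))
    stop("k_range must lie within [2, n - 1]")
  d <- stats::dist(m)
  set.seed(seed)
  res <- lapply(k_range, function(k) {
    km <- stats::kmeans(m, centers = k, nstart = n_init, iter.max = 100)
    sil <- cluster::silhouette(km$cluster, d)
    data.frame(k = k, inertia = km$tot.withinss,
               mean_silhouette = mean(sil[, "sil_width"]))
  })
  do.call(rbind, res)
}

#' Estimate surrogate variables by residual SVD
#'
#' Captures hidden technical structure (batches) orthogonal to the protected
#' experimental design: the variance-stabilized matrix (log-CPM) is
#' regressed on the protected design, the residuals are decomposed by SVD,
#' and the number of surrogate variables is the number of leading components
#' whose residual-variance fraction exceeds the 95th percentile of
#' row-permutation nulls (each null permutes the matrix within genes —
#' destroying sample structure while preserving gene variances — and is
#' re-residualized, the parallel-analysis construction). Residual right
#' singular vectors are orthogonal to the protected design by construction.
#'
#' @param counts Genes x samples count matrix (or logged values with
#'   \code{is_logged = TRUE}).
#' @param protected_design data.frame of protected covariates (experimental
#'   groups) or a design matrix.
#' @param n_sv \code{"auto"} (permutation selection) or a fixed integer.
#' @param n_perm Number of permutation nulls (default 100).
#' @param seed RNG seed.
#' @param is_logged Set TRUE when \code{counts} is already log-scale.
#' @return List: \code{sv} (samples x n_sv matrix, orthonormal),
#'   \code{n_sv}, \code{d_obs} (observed singular values),
#'   \code{var_fraction} (observed residual-variance fractions) and
#'   \code{var_fraction_q95} (per-component null thresholds).
#' @export
estimate_svs <- function(counts, protected_design, n_sv = "auto",
                         n_perm = 100, seed = 1L, is_logged = FALSE) {
  X <- if (is.data.frame(protected_design)) {
    stats::model.matrix(~., data = protected_design)
  } else as.matrix(protected_design)
  v <- if (is_logged) as.matrix(counts) else logcpm(counts)
  n <- ncol(v)
  if (n < ncol(X) + 2) stop("fewer residual degrees of freedom than 1")
  qx <- qr(X)
  H_resid <- function(M) M - t(qr.fitted(qx, t(M)))  # M (I - H)
  R <- H_resid(v)
  sv <- svd(R, nu = 0)
  d_obs <- sv$d
  f_obs <- d_obs^2 / sum(d_obs^2)
  max_sv <- n - qx$rank
  set.seed(seed)
  if (identical(n_sv, "auto")) {
    f_null <- matrix(NA_real_, n_perm, length(d_obs))
    for (b in seq_len(n_perm)) {
      dp <- svd(H_resid(t(apply(v, 1, sample))), nu = 0, nv = 0)$d
      f_null[b, ] <- dp^2 / sum(dp^2)
    }
    q95 <- apply(f_null, 2, stats::quantile, probs = 0.95)
    k <- 0
    while (k < max_sv && f_obs[k + 1] > q95[k + 1]) k <- k + 1
  } else {
    k <- min(as.integer(n_sv), max_sv)
    q95 <- rep(NA_real_, length(d_obs))
  }
  svs <- if (k > 0) sv$v[, seq_len(k), drop = FALSE]
         else matrix(numeric(0), nrow = n, ncol = 0)
  if (k > 0) {
    # defensive re-orthogonalization against the protected design
    svs <- svs - qr.fitted(qx, svs)
    svs <- qr.Q(qr(svs))
    colnames(svs) <- paste0("SV", seq_len(k))
    rownames(svs) <- colnames(v)
  }
  list(sv = svs, n_sv = k, d_obs = d_obs, var_fraction = f_obs,
       var_fraction_q95 = q95)
}

#' Surrogate-variable-adjusted meta-analysis across datasets
#'
#' Per-gene linear models on log-CPM. Additive mode fits
#' \code{~ SVs + condition} and tests the condition coefficient (shared
#' effect across datasets, with batch structure absorbed by the surrogate
#' variables); interactive mode fits \code{~ SVs + condition * dataset} and
#' additionally tests the condition-by-dataset interaction terms. Ordinary
#' (unmoderated) per-gene OLS tests; BH FDR per test family.
#'
#' @param counts Genes x samples counts (or logged with
#'   \code{is_logged = TRUE}) pooled across datasets.
#' @param condition Two-level factor (e.g. stress vs control).
#' @param dataset Factor identifying the dataset of each sample.
#' @param svs Samples x SV matrix (e.g. from \code{\link{estimate_svs}}), or
#'   NULL.
#' @param mode \code{"additive"} or \code{"interactive"}.
#' @param is_logged Set TRUE when \code{counts} is already log-scale.
#' @return data.frame with \code{feature, logfc, p_condition,
#'   fdr_condition} and, in interactive mode, \code{p_interaction,
#'   fdr_interaction}.
#' @export
meta_fit <- function(counts, condition, dataset, svs = NULL,
                     mode = c("additive", "interactive"),
                     is_logged = FALSE) {
  mode <- match.arg(mode)
  condition <- factor(condition)
  dataset <- factor(dataset)
  if (nlevels(condition) != 2) stop("condition must have two levels")
  v <- if (is_logged) as.matrix(counts) else logcpm(counts)
  Xs <- if (!is.null(svs) && ncol(as.matrix(svs)) > 0) as.matrix(svs)
        else NULL
  if (mode == "interactive") {
    if (nlevels(dataset) < 2) stop("interactive mode needs >= 2 datasets")
    if (any(table(condition, dataset) == 0))
      stop("condition is confounded with dataset (empty cell); aborting")
    Xf <- stats::model.matrix(~condition * dataset)
  } else {
    Xf <- stats::model.matrix(~condition)
  }
  X <- if (is.null(Xs)) Xf else cbind(Xf, Xs)
  if (qr(X)$rank < ncol(X))
    stop("design is rank deficient (condition aliased with SVs/dataset)")
  fit <- .ols_rows(v, X)
  s2 <- fit$rss / fit$df
  cc <- 2  # the condition main-effect column
  tval <- fit$coef[, cc] / sqrt(s2 * fit$xtx_inv[cc, cc])
  p_cond <- 2 * stats::pt(abs(tval), df = fit$df, lower.tail = FALSE)
  out <- data.frame(feature = rownames(v) %||% seq_len(nrow(v)),
                    logfc = fit$coef[, cc],
                    p_condition = p_cond,
                    fdr_condition = bh_fdr(p_cond), row.names = NULL)
  if (mode == "interactive") {
    int_cols <- grep(":", colnames(Xf))
    ft <- .drop_ftest(v, X, drop = int_cols, moderate = FALSE)
    out$p_interaction <- ft$p
    out$fdr_interaction <- bh_fdr(ft$p)
  }
  out
}
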