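#' Assign bulk DEGs to cell types from single-nucleus pseudo-bulks
#'
#' For each gene, the pseudo-bulk stress-control difference in every cell
#' type is weighted by its statistical support, \eqn{w_c = |\Delta_c| (1 -
#' p_c)}, and the gene is assigned to the cell type with the largest weight
#' among those whose difference has the same sign as the bulk change. The
#' assignment is called AMBIGUOUS when the top weight is less than
#' \code{ratio} times the second-largest weight over all cell types, and
#' NO_CONCORDANT when no cell type changes in the bulk direction.
#'
#' @param stress,control Genes x cell-types matrices of normalized
#'   pseudo-bulk expression.
#' @param pvals Genes x cell-types matrix of per-cell-type differential
#'   p-values; missing values are treated as p = 1 (no support) with a
#'   message.
#' @param bulk_sign Vector of +1/-1 bulk change directions per gene.
#' @param ratio Ambiguity ratio (default 2).
#' @param weight_mode \code{"linear"} (default): \eqn{w = |\Delta| (1-p)};
#'   \code{"power"}: \eqn{w = |\Delta|^{(1-p)}}, the alternative reading of
#'   the weighting rule.
#' @return data.frame with \code{gene_id, assigned} (cell type, AMBIGUOUS or
#'   NO_CONCORDANT), \code{w_top, w_second} and the top cell type's weighted
#'   difference columns.
#' @export
assign_celltypes <- function(stress, control, pvals, bulk_sign, ratio = 2,
                             weight_mode = c("linear", "power")) {
  weight_mode <- match.arg(weight_mode)
  stress <- as.matrix(stress); control <- as.matrix(control)
  pvals <- as.matrix(pvals)
  if (ncol(stress) < 2) stop("need >= 2 cell types")
  stopifnot(identical(dim(stress), dim(control)),
            identical(dim(stress), dim(pvals)),
            length(bulk_sign) == nrow(stress))
  if (anyNA(pvals)) {
    message(sum(is.na(pvals)), " missing p-value(s) treated as p = 1")
    pvals[is.na(pvals)] <- 1
  }
  if (any(pvals < 0 | pvals > 1)) stop("p-values must be in [0, 1]")
  delta <- stress - control
  w <- switch(weight_mode,
              linear = abs(delta) * (1 - pvals),
              power = abs(delta)^(1 - pvals))
  cts <- colnames(stress) %||% paste0("ct", seq_len(ncol(stress)))
  out <- data.frame(gene_id = rownames(stress) %||% seq_len(nrow(stress)),
                    assigned = NA_character_, w_top = NA_real_,
                    w_second = NA_real_, row.names = NULL)
  for (i in seq_len(nrow(stress))) {
    conc <- which(sign(delta[i, ]) == bulk_sign[i])
    if (length(conc) == 0) {
      out$assigned[i] <- "NO_CONCORDANT"
      next
    }
    top <- conc[which.max(w[i, conc])]
    w_top <- w[i, top]
    w_second <- max(w[i, -top])
    out$w_top[i] <- w_top
    out$w_second[i] <- w_second
    out$assigned[i] <- if (w_top < ratio * w_second) "AMBIGUOUS"
                       else cts[top]
  }
  out
}

#' Assign a single gene (convenience wrapper)
#'
#' @param stress,control,pvals Named numeric vectors over cell types.
#' @param bulk_sign +1 or -1.
#' @param ... Passed to \code{\link{assign_celltypes}}.
#' @return One-row assignment data.frame.
#' @export
assign_gene <- function(stress, control, pvals, bulk_sign, ...) {
  assign_celltypes(rbind(gene = stress), rbind(gene = control),
                   rbind(gene = pvals), bulk_sign, ...)
}

#' Summarize assignments by cell-type family
#'
#' Percentages of DEGs per family (e.g. neuronal, glial, vascular) over all
#' assigned plus ambiguous genes; NO_CONCORDANT genes are reported separately.
#'
#' @param assignments Output of \code{\link{assign_celltypes}}.
#' @param family_map Named character vector mapping cell type -> family.
#' @return data.frame with \code{family, n, pct}, including an AMBIGUOUS row;
#'   attribute \code{"n_no_concordant"}.
#' @export
assignment_summary <- function(assignments, family_map) {
  a <- assignments$assigned
  nc <- sum(a == "NO_CONCORDANT")
  a <- a[a != "NO_CONCORDANT"]
  if (length(a) == 0) stop("no assigned or ambiguous genes")
  fam <- ifelse(a == "AMBIGUOUS", "AMBIGUOUS", unname(family_map[a]))
  if (anyNA(fam))
    stop("cell type(s) without family mapping: ",
         paste(setdiff(unique(a[is.na(fam)]), "AMBIGUOUS"), collapse = ", "))
  tab <- table(fam)
  out <- data.frame(family = names(tab), n = as.integer(tab),
                    pct = 100 * as.integer(tab) / length(a),
                    row.names = NULL)
  attr(out, "n_no_concordant") <- nc
  out
}
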