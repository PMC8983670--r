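#' Classify read records under one of the three counting schemes
#'
#' Vectorized per-candidate acceptance filter. All schemes require a primary,
#' strand-concordant alignment with at most \code{non_overlap} bases matching
#' no candidate feature. Scheme "i" counts reads with exon overlap fraction
#' >= \code{frac_overlap} (junction-spanning reads allowed); scheme "ii" is
#' the same restricted to non-split reads; scheme "iii" uses the transcript
#' body as the feature, restricted to non-split reads. When a read overlaps
#' several genes (several candidate rows), resolution by largest overlap is
#' applied downstream by \code{\link{count_schemes}}.
#'
#' @param reads Read-record data.frame (one row per read x candidate gene)
#'   with columns \code{read_id, gene_id, split, exon_overlap_fraction,
#'   transcript_overlap_fraction, unmatched_bases, primary, strand_match}.
#' @param scheme One of "i", "ii", "iii".
#' @param frac_overlap Minimum overlap fraction (default 0.9).
#' @param non_overlap Maximum feature-unmatched bases (default 3).
#' @return Logical vector, one element per row of \code{reads}.
#' @export
classify_read <- function(reads, scheme, frac_overlap = 0.9,
                          non_overlap = 3) {
  if (!scheme %in% c("i", "ii", "iii"))
    stop("unknown scheme: ", scheme)
  frac <- if (scheme == "iii") reads$transcript_overlap_fraction
          else reads$exon_overlap_fraction
  if (any(frac < 0 | frac > 1)) stop("overlap fractions must be in [0,1]")
  ok <- reads$primary & reads$strand_match &
    reads$unmatched_bases <= non_overlap & frac >= frac_overlap
  if (scheme != "i") ok <- ok & !reads$split
  ok
}

#' Tally per-gene counts under the three schemes
#'
#' Applies \code{\link{classify_read}} for each scheme and assigns every
#' accepted read to a single gene. Reads with several accepted candidate
#' genes are resolved to the one with the largest relevant overlap fraction;
#' exact ties are left unassigned (never double-counted).
#'
#' @param reads Read-record table (see \code{\link{classify_read}}).
#' @return data.frame with \code{gene_id}, \code{exonic_all} (scheme i),
#'   \code{exonic_nonsplit} (scheme ii) and \code{transcript_nonsplit}
#'   (scheme iii).
#' @export
count_schemes <- function(reads) {
  genes <- sort(unique(reads$gene_id))
  tally <- function(scheme) {
    acc <- classify_read(reads, scheme)
    sub <- reads[acc, , drop = FALSE]
    if (nrow(sub) == 0) return(setNames(integer(length(genes)), genes))
    frac <- if (scheme == "iii") sub$transcript_overlap_fraction
            else sub$exon_overlap_fraction
    if (!anyDuplicated(sub$read_id)) {
      tab <- table(factor(sub$gene_id, levels = genes))
      return(setNames(as.integer(tab), genes))
    }
    # largest-overlap resolution across candidates of the same read
    best <- vapply(split(seq_len(nrow(sub)), sub$read_id), function(ix) {
      if (length(ix) == 1L) return(ix)
      f <- frac[ix]
      top <- which(f == max(f))
      if (length(top) > 1L) return(NA_integer_)  # tie -> unassigned
      ix[top]
    }, integer(1))
    best <- best[!is.na(best)]
    tab <- table(factor(sub$gene_id[best], levels = genes))
    setNames(as.integer(tab), genes)
  }
  data.frame(gene_id = genes,
             exonic_all = tally("i"),
             exonic_nonsplit = tally("ii"),
             transcript_nonsplit = tally("iii"),
             row.names = NULL)
}

#' Derive processed and unprocessed gene counts from the scheme triplet
#'
#' Processed counts are the standard exonic counts (scheme i). Unprocessed
#' counts are the non-split transcript-body counts minus the non-split
#' exonic counts (which are compatible with processed transcripts as well),
#' clamped at zero with a flag; negative differences only arise from
#' overlap-threshold asymmetries and are noise.
#'
#' @param triplets Output of \code{\link{count_schemes}}.
#' @return data.frame with \code{gene_id, processed, unprocessed, clamped}.
#' @export
derive_gene_counts <- function(triplets) {
  req <- c("gene_id", "exonic_all", "exonic_nonsplit", "transcript_nonsplit")
  if (!all(req %in% names(triplets))) stop("invalid triplet table")
  raw <- triplets$transcript_nonsplit - triplets$exonic_nonsplit
  clamped <- raw < 0
  if (any(clamped))
    message(sum(clamped), " gene(s) had negative unprocessed counts; clamped to 0")
  data.frame(gene_id = triplets$gene_id,
             processed = triplets$exonic_all,
             unprocessed = pmax(0L, raw),
             clamped = clamped, row.names = NULL)
}
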