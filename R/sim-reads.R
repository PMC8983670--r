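#' Build synthetic gene models (exon/intron structures)
#'
#' Lays out multi-exon gene models on a single synthetic chromosome,
#' 1-based closed coordinates (GTF convention). Genes are spaced so they
#' never overlap.
#'
#' @param n_genes Number of genes.
#' @param n_exons_range Integer range of exons per gene (inclusive).
#' @param exon_length_range,intron_length_range Length ranges in bases.
#' @param read_length Read length the models must accommodate (introns are
#'   drawn at least this long so fully intronic placement is possible).
#' @param seed RNG seed.
#' @return A data.frame with one row per exon: \code{gene_id, exon_rank,
#'   chrom, start, end, strand}, plus per-gene \code{gene_start, gene_end}.
#' @export
make_gene_models <- function(n_genes = 50, n_exons_range = c(2L, 6L),
                             exon_length_range = c(150L, 400L),
                             intron_length_range = c(500L, 3000L),
                             read_length = 100L, seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (min(intron_length_range) < read_length)
    stop("intron lengths must be >= read_length")
  set.seed(seed)
  # sample() treats a length-1 x as 1:x; always index explicitly
  resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
  gap <- 10000L
  pos <- 1L
  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    ne <- resample(seq(n_exons_range[1], n_exons_range[2]), 1)
    el <- resample(seq(exon_length_range[1], exon_length_range[2]), ne)
    il <- if (ne > 1) {
      resample(seq(intron_length_range[1], intron_length_range[2]), ne - 1)
    } else integer(0)
    starts <- integer(ne)
    ends <- integer(ne)
    p <- pos
    for (e in seq_len(ne)) {
      starts[e] <- p
      ends[e] <- p + el[e] - 1L
      p <- ends[e] + 1L
      if (e < ne) p <- p + il[e]
    }
    strand <- sample(c("+", "-"), 1)
    rows[[i]] <- data.frame(
      gene_id = sprintf("g%04d", i), exon_rank = seq_len(ne),
      chrom = "chrS", start = starts, end = ends, strand = strand,
      gene_start = starts[1], gene_end = ends[ne], row.names = NULL)
    pos <- ends[ne] + gap
  }
  do.call(rbind, rows)
}

# bases of [rs, re] covered by the exons of one gene (closed coordinates)
.exon_overlap_bases <- function(rs, re, ex_start, ex_end) {
  sum(pmax(0L, pmin(re, ex_end) - pmax(rs, ex_start) + 1L))
}

#' Simulate aligned-read feature-overlap records
#'
#' Emits one record per read with the overlap summaries the counting schemes
#' consume, plus a ground-truth origin label. Mature-origin reads are placed
#' uniformly on the spliced transcript (and are junction-spanning when they
#' cross an exon boundary); nascent-origin reads are placed uniformly on the
#' unspliced gene span, so they can be exonic, intronic or
#' boundary-crossing. Reads carry coordinates and overlap fractions, not
#' base strings. A configurable fraction of reads is marked non-primary,
#' strand-discordant, or carries clipped (feature-unmatched) bases, to
#' exercise the classifier's filters.
#'
#' @param gene_models Output of \code{\link{make_gene_models}}.
#' @param abundances data.frame with \code{gene_id}, \code{u} (nascent) and
#'   \code{s} (mature) abundance; reads are drawn gene- and origin-wise
#'   proportional to these.
#' @param n_reads Number of reads (> 0).
#' @param read_length Read length in bases.
#' @param frac_nonprimary,frac_strand_flip Fractions of reads flagged
#'   non-primary / strand-discordant.
#' @param clip_prob Probability a read carries clipped bases.
#' @param clip_max Maximum clipped bases (drawn uniformly on 1..clip_max).
#' @param seed RNG seed.
#' @return List with \code{reads} (the read-record table: \code{read_id,
#'   gene_id, split, exon_overlap_fraction, transcript_overlap_fraction,
#'   unmatched_bases, primary, strand_match}) and \code{truth}
#'   (\code{read_id, gene_id, origin} with origin nascent/mature).
#' @export
simulate_reads <- function(gene_models, abundances, n_reads,
                           read_length = 100L, frac_nonprimary = 0.02,
                           frac_strand_flip = 0.02, clip_prob = 0.05,
                           clip_max = 6L, seed = 1L) {
  if (n_reads <= 0) stop("n_reads must be > 0")
  set.seed(seed)
  gm <- split(gene_models, gene_models$gene_id)
  ab <- abundances[abundances$gene_id %in% names(gm), , drop = FALSE]
  if (nrow(ab) == 0) stop("no abundances match the gene models")

  # joint (gene, origin) sampling weights
  w <- c(ab$u, ab$s)
  pick <- sample.int(2L * nrow(ab), n_reads, replace = TRUE, prob = w)
  gene_i <- (pick - 1L) %% nrow(ab) + 1L
  origin <- ifelse(pick <= nrow(ab), "nascent", "mature")
  gene <- ab$gene_id[gene_i]

  recs <- vector("list", n_reads)
  for (r in seq_len(n_reads)) {
    g <- gm[[gene[r]]]
    ex_s <- g$start
    ex_e <- g$end
    span_s <- g$gene_start[1]
    span_e <- g$gene_end[1]
    if (origin[r] == "mature") {
      # uniform on the spliced transcript, mapped back to genomic blocks
      el <- ex_e - ex_s + 1L
      tl <- sum(el)
      if (tl < read_length) {
        tstart <- 1L
      } else {
        tstart <- sample.int(tl - read_length + 1L, 1L)
      }
      # exonic bases consumed per exon
      cum <- cumsum(el)
      remaining <- min(read_length, tl)
      pos <- tstart
      nblocks <- 0L
      p <- pos
      while (remaining > 0L) {
        e <- which(cum >= p)[1]
        off <- p - c(0L, cum)[e] - 1L
        take <- min(remaining, el[e] - off)
        nblocks <- nblocks + 1L
        p <- p + take
        remaining <- remaining - take
      }
      split <- nblocks > 1L
      exof <- 1
      trof <- 1
    } else {
      # uniform on the unspliced span
      gl <- span_e - span_s + 1L
      rs <- span_s + sample.int(gl - read_length + 1L, 1L) - 1L
      re <- rs + read_length - 1L
      ob <- .exon_overlap_bases(rs, re, ex_s, ex_e)
      split <- FALSE
      exof <- ob / read_length
      trof <- 1
    }
    unmatched <- 0L
    if (runif(1) < clip_prob) {
      unmatched <- sample.int(clip_max, 1L)
      sc <- (read_length - unmatched) / read_length
      exof <- exof * sc
      trof <- trof * sc
    }
    recs[[r]] <- c(split = split, exof = exof, trof = trof,
                   unmatched = unmatched)
  }
  m <- do.call(rbind, recs)
  reads <- data.frame(
    read_id = sprintf("r%06d", seq_len(n_reads)),
    gene_id = gene,
    split = as.logical(m[, "split"]),
    exon_overlap_fraction = m[, "exof"],
    transcript_overlap_fraction = m[, "trof"],
    unmatched_bases = as.integer(m[, "unmatched"]),
    primary = runif(n_reads) >= frac_nonprimary,
    strand_match = runif(n_reads) >= frac_strand_flip,
    row.names = NULL)
  truth <- data.frame(read_id = reads$read_id, gene_id = gene,
                      origin = origin, row.names = NULL)
  list(reads = reads, truth = truth)
}
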