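#' Write a simulated run to a directory with a manifest
#'
#' Emits the bulk simulation as plain-text artifacts under \code{dir}:
#' count matrices as TSV and MatrixMarket (with row/column sidecars), the
#' truth table and sample metadata as TSV, optional gene models as GTF
#' (requires the rtracklayer package), and a YAML manifest recording the
#' configuration, seed and file list.
#'
#' @param sim Output of \code{\link{simulate_bulk_counts}}.
#' @param dir Output directory (created if needed).
#' @param design The \code{\link{course_design}} used (recorded in the
#'   manifest).
#' @param gene_models Optional \code{\link{make_gene_models}} table; when
#'   given and rtracklayer is installed, written as \code{genes.gtf}.
#' @param reads Optional read-record table, written as \code{reads.tsv}.
#' @return Invisibly, the manifest list.
#' @export
write_sim_run <- function(sim, dir, design = NULL, gene_models = NULL,
                          reads = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wtsv <- function(x, name, rows = FALSE) {
    path <- file.path(dir, name)
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = rows, col.names = TRUE)
    files <<- c(files, name)
  }
  for (frac in c("processed", "unprocessed")) {
    m <- sim[[frac]]
    wtsv(m, paste0(frac, "_counts.tsv"), rows = TRUE)
    mm <- paste0(frac, "_counts.mtx")
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), file.path(dir, mm))
    writeLines(rownames(m), file.path(dir, paste0(frac, "_counts.rows")))
    writeLines(colnames(m), file.path(dir, paste0(frac, "_counts.cols")))
    files <- c(files, mm, paste0(frac, "_counts.rows"),
               paste0(frac, "_counts.cols"))
  }
  wtsv(sim$samples, "samples.tsv")
  wtsv(sim$truth, "truth.tsv")
  if (!is.null(reads)) wtsv(reads, "reads.tsv")
  if (!is.null(gene_models)) {
    if (requireNamespace("rtracklayer", quietly = TRUE) &&
        requireNamespace("GenomicRanges", quietly = TRUE)) {
      gr <- GenomicRanges::GRanges(
        seqnames = gene_models$chrom,
        ranges = IRanges::IRanges(gene_models$start, gene_models$end),
        strand = gene_models$strand)
      gr$type <- "exon"
      gr$gene_id <- gene_models$gene_id
      gr$transcript_id <- paste0(gene_models$gene_id, ".t1")
      gr$exon_number <- gene_models$exon_rank
      rtracklayer::export(gr, file.path(dir, "genes.gtf"), format = "gtf")
      files <- c(files, "genes.gtf")
    } else {
      message("rtracklayer not available; skipping GTF export")
    }
  }
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = if (!is.null(design)) design$seed else NA_integer_,
    design = if (!is.null(design)) {
      list(timepoints = design$timepoints, regions = design$regions,
           n_replicates = design$n_replicates,
           library_size = design$library_size,
           nb_dispersion = design$nb_dispersion)
    },
    files = files)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a TSV count matrix written by \code{\link{write_sim_run}}
#'
#' @param path Path to a \code{*_counts.tsv} file.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
}
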