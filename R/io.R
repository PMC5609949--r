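#' Write a reference genome as FASTA
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, format = "fasta")
  invisible(path)
}

#' Write gene models as BED6 or GTF
#'
#' BED6 uses 0-based half-open coordinates with `name = gene_id` and
#' `score = 0`; GTF uses 1-based inclusive coordinates with one `gene`
#' feature per model. Both conversions are handled by rtracklayer.
#'
#' @param genes [GenomicRanges::GRanges] with `gene_id`.
#' @param path output path; format from `format`.
#' @param format `"bed"` or `"gtf"`.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  g <- genes
  if (format == "bed") {
    g$name <- g$gene_id
    g$score <- 0L
    g$gene_id <- NULL
    rtracklayer::export(g, path, format = "BED")
  } else {
    g$source <- "trapscreen"
    g$type <- "gene"
    rtracklayer::export(g, path, format = "gtf")
  }
  invisible(path)
}

#' Read gene models from GTF or BED
#'
#' GTF (1-based inclusive) and BED (0-based half-open) are converted to
#' the internal 1-based inclusive representation by rtracklayer. For
#' GTF input only `gene` features are kept when a `type` column is
#' present; for BED the `name` column becomes `gene_id`.
#'
#' @param path GTF or BED file.
#' @return [GenomicRanges::GRanges] with a `gene_id` column.
#' @export
read_genes <- function(path) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GTF"
  g <- rtracklayer::import(path, format = fmt)
  if (fmt == "BED") {
    g$gene_id <- g$name
  } else if (!is.null(g$type) && any(g$type == "gene")) {
    g <- g[g$type == "gene"]
  }
  if (is.null(g$gene_id)) stop("no gene identifiers found in ", path)
  g
}

#' Write reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(
    vapply(Biostrings::width(reads), function(w) {
      strrep("I", w)
    }, character(1))
  )
  Biostrings::writeXStringSet(
    reads, path, format = "fastq", qualities = quals
  )
  invisible(path)
}

#' Write a table as TSV with '#'-prefixed metadata lines
#'
#' The interchange format between pipeline stages: a plain TSV whose
#' header is preceded by comment lines recording provenance (package
#' version, seed, parameters), so outputs stay diff-able and
#' spreadsheet-safe while carrying their run manifest.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named character vector or list of metadata entries.
#' @return `path`, invisibly.
#' @export
write_tsv_with_meta <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf(
    "# trapscreen %s", as.character(packageVersion("trapscreen"))
  ), con)
  for (k in names(meta)) {
    writeLines(sprintf("# %s=%s", k, as.character(meta[[k]])), con)
  }
  write.table(
    df, con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a TSV written by [write_tsv_with_meta()]
#'
#' @param path input path.
#' @return data.frame; '#'-prefixed lines are skipped.
#' @export
read_tsv_with_meta <- function(path) {
  read.delim(
    path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE
  )
}

#' Write insertion sites as BED6
#'
#' One BED record per site: `name = gene_id|orientation` (empty gene_id
#' written as "."), `score = read_count`, strand = provirus strand.
#'
#' @param sites annotated site data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$position, width = 1L),
    strand = sites$strand,
    name = paste(
      ifelse(sites$gene_id == "", ".", sites$gene_id),
      sites$orientation,
      sep = "|"
    ),
    score = sites$read_count
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
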