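#' Align junction-flanking reads against a reference by exact search
#'
#' Desk-scale ungapped aligner for gene-trap flanking reads: each read
#' is searched full-length against both strands of the reference. When
#' at least one exact placement exists, `n_placements` counts the exact
#' placements and `n_mismatches` is 0. When no exact placement exists,
#' the best placement (fewest substitutions) is reported so the strict
#' filter can account for it. Externally produced alignments can be
#' supplied instead via [read_alignments()].
#'
#' @param reads a named [Biostrings::DNAStringSet] or path to a FASTQ
#'   file.
#' @param genome a named [Biostrings::DNAStringSet] (one sequence) or
#'   path to a FASTA file.
#' @return data.frame with columns `read_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`, `n_mismatches`, `n_placements`.
#' @export
align_reads <- function(reads, genome) {
  if (is.character(reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  }
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome, format = "fasta")
  }
  if (length(genome) == 0L || Biostrings::nchar(genome)[1] == 0L) {
    stop("empty genome")
  }
  if (length(reads) == 0L) {
    return(empty_alignments())
  }
  widths <- Biostrings::width(reads)
  if (any(widths == 0L)) stop("empty read")
  gseq <- genome[[1]]
  glen <- length(gseq)
  if (any(widths >= glen)) {
    stop("all reads must be shorter than the genome")
  }
  chrom <- names(genome)[1]
  seqs <- as.character(reads)
  uniq <- unique(seqs)
  hit <- lapply(uniq, function(s) place_read(s, gseq))
  idx <- match(seqs, uniq)
  starts <- vapply(hit, `[[`, numeric(1), "start")[idx]
  data.frame(
    read_id = names(reads) %||% sprintf("read%06d", seq_along(reads)),
    chrom = chrom,
    start = as.integer(starts),
    end = as.integer(starts + widths - 1L),
    strand = vapply(hit, `[[`, character(1), "strand")[idx],
    n_mismatches = vapply(hit, `[[`, numeric(1), "nm")[idx],
    n_placements = vapply(hit, `[[`, numeric(1), "np")[idx],
    stringsAsFactors = FALSE
  )
}

# exact placements first; fall back to a full scan for the best
# substitution-only placement on either strand
place_read <- function(seq, gseq) {
  pat <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(pat)
  fwd <- Biostrings::matchPattern(pat, gseq)
  rev <- Biostrings::matchPattern(rc, gseq)
  np <- length(fwd) + length(rev)
  if (np > 0L) {
    if (length(fwd) > 0L) {
      return(list(
        start = Biostrings::start(fwd)[1], strand = "+", nm = 0, np = np
      ))
    }
    return(list(
      start = Biostrings::start(rev)[1], strand = "-", nm = 0, np = np
    ))
  }
  w <- length(pat)
  at <- seq_len(length(gseq) - w + 1L)
  ed_f <- Biostrings::neditStartingAt(pat, gseq, starting.at = at)
  ed_r <- Biostrings::neditStartingAt(rc, gseq, starting.at = at)
  best <- min(ed_f, ed_r)
  n_best <- sum(ed_f == best) + sum(ed_r == best)
  if (any(ed_f == best)) {
    list(
      start = at[which(ed_f == best)[1]], strand = "+",
      nm = best, np = n_best
    )
  } else {
    list(
      start = at[which(ed_r == best)[1]], strand = "-",
      nm = best, np = n_best
    )
  }
}

empty_alignments <- function() {
  data.frame(
    read_id = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    n_mismatches = numeric(0), n_placements = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Read external alignments from a SAM file
#'
#' Interoperability with any external aligner. SAM fields are mapped to
#' the package's alignment table: `n_mismatches` is taken from the NM
#' tag (records without NM are kept with `n_mismatches = NA` and later
#' discarded by the strict filter — unknown is not zero); uniqueness is
#' approximated as `n_placements = 1` when mapping quality is positive
#' and no secondary record shares the read name, else 2. Unmapped
#' records are dropped and counted in the `n_unmapped` attribute.
#'
#' @param sam path to a plain-text SAM file with sequence headers.
#' @return alignment data.frame as in [align_reads()]; attributes
#'   `n_unmapped` and `n_missing_nm` carry skip accounting.
#' @export
read_alignments <- function(sam) {
  if (!file.exists(sam)) stop("SAM file not found: ", sam)
  bam <- tryCatch(
    Rsamtools::asBam(
      sam, destination = tempfile(), overwrite = TRUE,
      indexDestination = FALSE
    ),
    error = function(e) {
      stop("malformed SAM '", sam, "': ", conditionMessage(e))
    }
  )
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"), tag = "NM"
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  meta <- S4Vectors::mcols(ga)
  n_unmapped <- Rsamtools::countBam(
    bam,
    param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)
    )
  )$records
  secondary <- bitwAnd(meta$flag, 256L) > 0L
  multi_names <- unique(meta$qname[secondary])
  keep <- !secondary
  nm <- meta$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(ga))
  gr <- methods::as(ga, "GRanges")
  out <- data.frame(
    read_id = meta$qname[keep],
    chrom = as.character(GenomicRanges::seqnames(gr))[keep],
    start = GenomicRanges::start(gr)[keep],
    end = GenomicRanges::end(gr)[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    n_mismatches = as.numeric(nm[keep]),
    n_placements = ifelse(
      meta$mapq[keep] > 0L & !(meta$qname[keep] %in% multi_names), 1, 2
    ),
    stringsAsFactors = FALSE
  )
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_missing_nm") <- sum(is.na(out$n_mismatches))
  out
}

#' Keep only uniquely aligned zero-mismatch reads
#'
#' The screen's read-level filter: an alignment is retained exactly when
#' it has zero mismatches and a single best placement. Alignments with
#' unknown mismatch counts (no NM tag) are discarded — the filter is
#' strict. Discard counts by reason are attached as the `filter_stats`
#' attribute.
#'
#' @param alignments alignment data.frame from [align_reads()] or
#'   [read_alignments()].
#' @return the retained rows, with a `filter_stats` attribute listing
#'   `retained`, `discarded_mismatch`, `discarded_multimapped` and
#'   `discarded_unknown_nm`.
#' @export
filter_alignments <- function(alignments) {
  nm <- alignments$n_mismatches
  np <- alignments$n_placements
  unknown <- is.na(nm)
  mism <- !unknown & nm > 0
  multi <- !unknown & nm == 0 & np != 1
  keep <- !unknown & nm == 0 & np == 1
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_stats") <- c(
    retained = sum(keep),
    discarded_mismatch = sum(mism),
    discarded_multimapped = sum(multi),
    discarded_unknown_nm = sum(unknown)
  )
  out
}

#' Collapse filtered alignments to deduplicated insertion sites
#'
#' Derives the LTR-genome junction from each alignment — the leftmost
#' aligned base for a plus-strand read, the rightmost for a minus-strand
#' read (inverse-PCR reads start at the junction) — and groups reads by
#' `(chrom, junction, strand)`. Each group is one unique insertion site;
#' its `read_count` is the group size.
#'
#' @param alignments filtered alignment data.frame.
#' @return site data.frame with columns `chrom`, `position` (1-based
#'   junction base), `strand`, `read_count`, sorted by chrom, position,
#'   strand.
#' @export
collapse_to_sites <- function(alignments) {
  if (nrow(alignments) == 0L) {
    return(empty_sites())
  }
  junction <- ifelse(
    alignments$strand == "+", alignments$start, alignments$end
  )
  key <- paste(alignments$chrom, junction, alignments$strand, sep = "\r")
  counts <- table(key)
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1),
    position = as.integer(vapply(parts, `[[`, character(1), 2)),
    strand = vapply(parts, `[[`, character(1), 3),
    read_count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_sites <- function() {
  data.frame(
    chrom = character(0), position = integer(0), strand = character(0),
    read_count = integer(0), stringsAsFactors = FALSE
  )
}

#' Collapse simulated surviving insertions to sites
#'
#' Ground-truth counterpart of [collapse_to_sites()]: aggregates
#' surviving library records by `(chrom, position, strand)`, summing
#' read counts, so simulator output can enter the enrichment stage
#' directly (or be compared with sites recovered from reads).
#'
#' @param survivors data.frame from [simulate_selection()].
#' @return site data.frame as in [collapse_to_sites()].
#' @export
survivor_sites <- function(survivors) {
  if (nrow(survivors) == 0L) {
    return(empty_sites())
  }
  agg <- stats::aggregate(
    read_count ~ chrom + position + strand,
    data = survivors, FUN = sum
  )
  agg$position <- as.integer(agg$position)
  agg$read_count <- as.integer(agg$read_count)
  agg <- agg[
    order(agg$chrom, agg$position, agg$strand),
    c("chrom", "position", "strand", "read_count"),
    drop = FALSE
  ]
  rownames(agg) <- NULL
  agg
}

#' Annotate insertion sites with gene and orientation
#'
#' A site whose junction base falls inside a gene's interval (full
#' transcript body, introns included — gene traps act intronically) is
#' assigned that gene; its orientation is `sense` when the provirus
#' strand equals the gene strand (the inactivating configuration), else
#' `antisense`. Sites outside all genes are `intergenic` with an empty
#' `gene_id`. A site inside several overlapping genes yields one record
#' per gene. Sites on chromosomes absent from the annotation are
#' annotated intergenic and counted in the `n_unknown_chrom` attribute.
#'
#' @param sites site data.frame from [collapse_to_sites()] or
#'   [survivor_sites()].
#' @param genes gene models as a [GenomicRanges::GRanges] with
#'   `gene_id`.
#' @return the sites with `gene_id` and `orientation` columns (possibly
#'   more rows than input if genes overlap).
#' @export
annotate_orientation <- function(sites, genes) {
  if (nrow(sites) == 0L) {
    out <- cbind(
      empty_sites(),
      data.frame(gene_id = character(0), orientation = character(0))
    )
    return(out)
  }
  known <- as.character(GenomicRanges::seqnames(genes))
  unknown_chrom <- !(sites$chrom %in% known)
  gene_rows <- NULL
  in_gene <- logical(nrow(sites))
  if (length(genes) > 0L) {
    q <- GenomicRanges::GRanges(
      seqnames = sites$chrom,
      ranges = IRanges::IRanges(start = sites$position, width = 1L)
    )
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
      q, genes, ignore.strand = TRUE
    ))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    in_gene[unique(qi)] <- TRUE
    if (length(qi) > 0L) {
      gene_rows <- sites[qi, , drop = FALSE]
      gene_rows$gene_id <- genes$gene_id[si]
      gstrand <- as.character(GenomicRanges::strand(genes))[si]
      gene_rows$orientation <- ifelse(
        gene_rows$strand == gstrand, "sense", "antisense"
      )
    }
  }
  inter <- sites[!in_gene, , drop = FALSE]
  if (nrow(inter) > 0L) {
    inter$gene_id <- ""
    inter$orientation <- "intergenic"
  } else {
    inter$gene_id <- character(0)
    inter$orientation <- character(0)
  }
  out <- rbind(gene_rows, inter)
  out <- out[order(out$chrom, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unknown_chrom") <- sum(unknown_chrom)
  out
}

#' Map reads (or external alignments) to annotated insertion sites
#'
#' One-call mapping stage: align FASTQ reads with the built-in exact
#' matcher (or ingest a SAM file), apply the unique zero-mismatch
#' filter, collapse to sites and annotate orientation against the gene
#' models.
#'
#' @param reads FASTQ path or [Biostrings::DNAStringSet]; ignored when
#'   `sam` is given.
#' @param genome FASTA path or [Biostrings::DNAStringSet]; required
#'   with `reads`.
#' @param sam optional SAM path of externally produced alignments.
#' @param genes gene models ([GenomicRanges::GRanges] with `gene_id`)
#'   or a GTF/BED path.
#' @return annotated site data.frame; the `filter_stats` attribute
#'   carries the read-filter accounting.
#' @export
map_insertions <- function(reads = NULL, genome = NULL, sam = NULL,
                           genes) {
  if (is.character(genes)) genes <- read_genes(genes)
  aln <- if (!is.null(sam)) {
    read_alignments(sam)
  } else {
    if (is.null(reads) || is.null(genome)) {
      stop("either `sam` or both `reads` and `genome` must be given")
    }
    align_reads(reads, genome)
  }
  flt <- filter_alignments(aln)
  sites <- annotate_orientation(collapse_to_sites(flt), genes)
  attr(sites, "filter_stats") <- attr(flt, "filter_stats")
  sites
}
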