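#' Screen simulation configuration
#'
#' Bundles every parameter of the gene-trap screen simulator. Defaults
#' describe a desk-scale analogue of a near-haploid resistance screen:
#' a toy genome with 50 genes, 2e4 independently mutagenized cells per
#' arm, one resistance gene whose sense-orientation disruption confers
#' survival under drug selection, and heavy-tailed per-site read counts
#' emulating clonal expansion plus inverse-PCR amplification skew.
#'
#' @param genome_length genome size in bases.
#' @param n_genes number of non-overlapping gene models to place.
#' @param n_cells number of mutagenized cells in the selected arm.
#' @param n_control_cells number of cells in the unselected control arm
#'   (its sequencing depth relative to the selected pool is a free
#'   parameter of the design).
#' @param resistance_genes character vector of gene identifiers whose
#'   sense-orientation disruption confers drug resistance.
#' @param p_survive_resistant survival probability for cells with a
#'   sense insertion in a resistance gene.
#' @param p_survive_background survival probability for all other cells.
#' @param readcount_log_mean,readcount_log_sd meanlog and sdlog of the
#'   log-normal per-site read-count law (counts are rounded up, so every
#'   surviving site has at least one read).
#' @param read_length junction-flanking read length in bases (>= 20).
#' @param seed integer master seed; fanned out to fixed per-stage seeds.
#' @return a `screen_sim_config` list, validated.
#' @export
screen_sim_config <- function(genome_length = 100000L,
                              n_genes = 50L,
                              n_cells = 20000L,
                              n_control_cells = n_cells,
                              resistance_genes = "gene001",
                              p_survive_resistant = 0.95,
                              p_survive_background = 1e-3,
                              readcount_log_mean = 3,
                              readcount_log_sd = 2,
                              read_length = 36L,
                              seed = 1L) {
  if (genome_length <= 0) stop("`genome_length` must be positive")
  stopifnot_scalar_prob(p_survive_resistant, "p_survive_resistant")
  stopifnot_scalar_prob(p_survive_background, "p_survive_background")
  if (p_survive_background > p_survive_resistant) {
    stop("`p_survive_background` must not exceed `p_survive_resistant`")
  }
  if (read_length < 20) stop("`read_length` must be at least 20 bases")
  if (n_cells < 1 || n_control_cells < 1) {
    stop("cell counts must be at least 1")
  }
  structure(
    list(
      genome_length = as.integer(genome_length),
      n_genes = as.integer(n_genes),
      n_cells = as.integer(n_cells),
      n_control_cells = as.integer(n_control_cells),
      resistance_genes = as.character(resistance_genes),
      p_survive_resistant = p_survive_resistant,
      p_survive_background = p_survive_background,
      readcount_log_mean = readcount_log_mean,
      readcount_log_sd = readcount_log_sd,
      read_length = as.integer(read_length),
      seed = as.integer(seed)
    ),
    class = "screen_sim_config"
  )
}

#' Generate a toy reference genome with non-overlapping gene models
#'
#' Places `n_genes` disjoint genes of random length and strand on a
#' uniformly random nucleotide sequence. Genes jointly cover at most
#' 80% of the sequence; each gene sits inside its own equal-width slot,
#' which guarantees disjointness by construction.
#'
#' @param length genome length in bases; must be at least `50 * n_genes`.
#' @param n_genes number of genes (0 allowed).
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with `genome` (a named [Biostrings::DNAStringSet] of one
#'   sequence, "chr1") and `genes` (a [GenomicRanges::GRanges] with a
#'   `gene_id` metadata column; 1-based inclusive coordinates).
#' @export
generate_genome <- function(length, n_genes, seed = 1L) {
  length <- as.integer(length)
  n_genes <- as.integer(n_genes)
  if (length <= 0) stop("`length` must be positive")
  if (n_genes < 0) stop("`n_genes` must be non-negative")
  if (n_genes > 0 && length < 50L * n_genes) {
    stop(
      "infeasible packing: ", n_genes, " genes cannot fit in ",
      length, " bases (need at least ", 50L * n_genes, ")"
    )
  }
  with_seed(seed, {
    seq <- paste(
      sample(c("A", "C", "G", "T"), length, replace = TRUE),
      collapse = ""
    )
    genome <- Biostrings::DNAStringSet(seq)
    names(genome) <- "chr1"
    if (n_genes == 0L) {
      genes <- GenomicRanges::GRanges(gene_id = character(0))
      return(list(genome = genome, genes = genes))
    }
    slot <- length %/% n_genes
    # cap gene length at 70% of the slot: total coverage <= 70% < 80%
    glen <- pmax(20L, as.integer(floor(slot * runif(n_genes, 0.3, 0.7))))
    offset <- vapply(
      slot - glen,
      function(room) as.integer(floor(runif(1, 0, room + 1))),
      integer(1)
    )
    starts <- (seq_len(n_genes) - 1L) * slot + offset + 1L
    genes <- GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(start = starts, end = starts + glen - 1L),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      gene_id = sprintf("gene%03d", seq_len(n_genes))
    )
    list(genome = genome, genes = genes)
  })
}

#' Simulate a mutagenized single-insertion library
#'
#' Each cell carries exactly one gene-trap insertion (the near-haploid
#' single-integration assumption) at a uniformly random genomic position
#' with a uniformly random provirus strand. The insertion position is the
#' 1-based coordinate of the first genomic base 3' of the LTR-genome
#' junction. Each record is annotated sense / antisense / intergenic
#' against the gene models.
#'
#' @param genome named [Biostrings::DNAStringSet] (one sequence).
#' @param genes gene models as a [GenomicRanges::GRanges] with `gene_id`.
#' @param n_cells number of cells (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `cell_id`, `chrom`, `position`,
#'   `strand`, `gene_id`, `orientation`.
#' @export
simulate_insertion_library <- function(genome, genes, n_cells, seed = 1L) {
  glen <- genome_length_of(genome)
  if (glen == 0L) stop("empty genome")
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("`n_cells` must be at least 1")
  chrom <- names(genome)[1]
  with_seed(seed, {
    lib <- data.frame(
      cell_id = sprintf("cell%06d", seq_len(n_cells)),
      chrom = chrom,
      position = sample.int(glen, n_cells, replace = TRUE),
      strand = sample(c("+", "-"), n_cells, replace = TRUE),
      stringsAsFactors = FALSE
    )
    ann <- annotate_positions(lib$chrom, lib$position, lib$strand, genes)
    lib$gene_id <- ann$gene_id
    lib$orientation <- ann$orientation
    lib
  })
}

#' Apply drug selection and draw per-site read counts
#'
#' A cell survives selection with probability `p_survive_resistant` if
#' its insertion is in the sense orientation inside a resistance gene,
#' and with probability `p_survive_background` otherwise. Each surviving
#' insertion receives a log-normal read count rounded up to at least 1,
#' emulating clonal expansion during selection and inverse-PCR skew.
#'
#' @param library data.frame from [simulate_insertion_library()].
#' @param config a [screen_sim_config()].
#' @return the surviving rows of `library` with a `read_count` column.
#' @export
simulate_selection <- function(library, config) {
  if (!inherits(config, "screen_sim_config")) {
    stop("`config` must be a screen_sim_config")
  }
  if (nrow(library) == 0L) stop("`library` must be nonempty")
  with_seed(fan_seed(config$seed, "selection"), {
    resistant <- library$orientation == "sense" &
      library$gene_id %in% config$resistance_genes
    p <- ifelse(
      resistant, config$p_survive_resistant, config$p_survive_background
    )
    keep <- rbinom(nrow(library), 1L, p) == 1L
    survivors <- library[keep, , drop = FALSE]
    survivors$read_count <- as.integer(ceiling(rlnorm(
      nrow(survivors),
      meanlog = config$readcount_log_mean,
      sdlog = config$readcount_log_sd
    )))
    rownames(survivors) <- NULL
    survivors
  })
}

#' Emit junction-flanking reads for surviving insertion sites
#'
#' For each surviving insertion the simulator emits `read_count` copies
#' of the genomic sequence immediately 3' of the LTR-genome junction on
#' the provirus strand: for a plus-strand insertion at position p the
#' read is `genome[p .. p+L-1]`; for a minus-strand insertion it is the
#' reverse complement of `genome[p-L+1 .. p]`. Sites too close to a
#' sequence end for a full-length read are skipped with a warning.
#' Per-base substitutions are applied at `mismatch_rate`. Read names
#' encode the true site (`chrom:position:strand:copy`) for round-trip
#' testing.
#'
#' @param survivors data.frame from [simulate_selection()] (needs
#'   `chrom`, `position`, `strand`, `read_count`).
#' @param genome named [Biostrings::DNAStringSet].
#' @param read_length read length in bases (<= genome length).
#' @param mismatch_rate per-base substitution probability.
#' @param seed integer seed.
#' @return a named [Biostrings::DNAStringSet]; the `skipped_sites`
#'   attribute holds the rows skipped for lying too close to an end.
#' @export
generate_reads <- function(survivors, genome, read_length,
                           mismatch_rate = 0, seed = 1L) {
  glen <- genome_length_of(genome)
  read_length <- as.integer(read_length)
  if (read_length > glen) stop("`read_length` exceeds genome length")
  stopifnot_scalar_prob(mismatch_rate, "mismatch_rate")
  plus <- survivors$strand == "+"
  ok <- ifelse(
    plus,
    survivors$position + read_length - 1L <= glen,
    survivors$position >= read_length
  )
  skipped <- survivors[!ok, , drop = FALSE]
  if (nrow(skipped) > 0L) {
    warning(
      nrow(skipped), " site(s) too close to a sequence end for a ",
      read_length, "-base read; skipped"
    )
  }
  kept <- survivors[ok, , drop = FALSE]
  if (nrow(kept) == 0L) {
    out <- Biostrings::DNAStringSet()
    attr(out, "skipped_sites") <- skipped
    return(out)
  }
  with_seed(seed, {
    seqs <- character(nrow(kept))
    gseq <- genome[[1]]
    for (i in seq_len(nrow(kept))) {
      p <- kept$position[i]
      if (kept$strand[i] == "+") {
        s <- Biostrings::subseq(gseq, p, p + read_length - 1L)
      } else {
        s <- Biostrings::reverseComplement(
          Biostrings::subseq(gseq, p - read_length + 1L, p)
        )
      }
      seqs[i] <- as.character(s)
    }
    counts <- kept$read_count
    reads <- rep(seqs, counts)
    ids <- paste0(
      rep(kept$chrom, counts), ":",
      rep(kept$position, counts), ":",
      rep(kept$strand, counts), ":",
      sequence(counts)
    )
    if (mismatch_rate > 0 && length(reads) > 0L) {
      mat <- matrix(
        unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
        nrow = read_length
      )
      hit <- which(runif(length(mat)) < mismatch_rate)
      if (length(hit) > 0L) {
        bases <- c("A", "C", "G", "T")
        for (j in hit) {
          mat[j] <- sample(setdiff(bases, mat[j]), 1L)
        }
        reads <- apply(mat, 2, paste, collapse = "")
      }
    }
    out <- Biostrings::DNAStringSet(reads)
    names(out) <- ids
    attr(out, "skipped_sites") <- skipped
    out
  })
}

#' Simulate a full screen: genome, arms, selection, truth
#'
#' Convenience orchestration of the generator: builds the genome and
#' gene models, mutagenizes a selected and an independent unselected
#' control arm, applies drug selection to the selected arm only, and
#' draws sequencing read counts for both arms.
#'
#' @param config a [screen_sim_config()].
#' @return list with `genome`, `genes`, `selected` and `control`
#'   (surviving insertion records with read counts), and `config`.
#' @export
simulate_screen <- function(config = screen_sim_config()) {
  gg <- generate_genome(
    config$genome_length, config$n_genes,
    seed = fan_seed(config$seed, "genome")
  )
  bad <- setdiff(config$resistance_genes, gg$genes$gene_id)
  if (length(bad) > 0L) {
    stop("resistance gene(s) not in generated gene set: ",
         paste(bad, collapse = ", "))
  }
  sel_lib <- simulate_insertion_library(
    gg$genome, gg$genes, config$n_cells,
    seed = fan_seed(config$seed, "library")
  )
  ctl_lib <- simulate_insertion_library(
    gg$genome, gg$genes, config$n_control_cells,
    seed = fan_seed(config$seed, "library") + 1L
  )
  selected <- simulate_selection(sel_lib, config)
  # the control arm is the unselected mutagenized library: no selection,
  # but its sequencing is subject to the same read-count law
  ctl_config <- config
  ctl_config$p_survive_resistant <- 1
  ctl_config$p_survive_background <- 1
  ctl_config$seed <- config$seed + 1L
  control <- simulate_selection(ctl_lib, ctl_config)
  list(
    genome = gg$genome, genes = gg$genes,
    selected = selected, control = control, config = config
  )
}

genome_length_of <- function(genome) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (length(genome) == 0L) return(0L)
  Biostrings::nchar(genome)[1]
}

# shared annotation core: sense iff provirus strand equals gene strand
annotate_positions <- function(chrom, position, strand, genes) {
  n <- length(position)
  gene_id <- character(n)
  orientation <- rep("intergenic", n)
  if (length(genes) > 0L && n > 0L) {
    q <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = position, width = 1L)
    )
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
      q, genes, ignore.strand = TRUE
    ))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    # one insertion per cell: genes are non-overlapping here, keep first
    first <- !duplicated(qi)
    qi <- qi[first]
    si <- si[first]
    gene_id[qi] <- genes$gene_id[si]
    gstrand <- as.character(GenomicRanges::strand(genes))[si]
    orientation[qi] <- ifelse(strand[qi] == gstrand, "sense", "antisense")
  }
  data.frame(
    gene_id = gene_id, orientation = orientation, stringsAsFactors = FALSE
  )
}
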