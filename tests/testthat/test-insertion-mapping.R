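test_that("align_reads agrees with a brute-force scan of both strands", {
  set.seed(21)
  gstr <- paste(
    sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = ""
  )
  genome <- Biostrings::DNAStringSet(gstr)
  names(genome) <- "chr1"

  # unique exact substring
  r_unique <- substr(gstr, 101, 130)
  # substring occurring twice: duplicate a block
  g2 <- paste0(gstr, substr(gstr, 201, 260))
  genome2 <- Biostrings::DNAStringSet(g2)
  names(genome2) <- "chr1"
  r_twice <- substr(gstr, 211, 240)
  # reverse complement of a unique substring
  r_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gstr, 301, 330))
  ))

  reads <- Biostrings::DNAStringSet(c(a = r_unique, b = r_rc))
  aln <- align_reads(reads, genome)
  expect_equal(aln$n_mismatches, c(0, 0))
  expect_equal(aln$n_placements, c(1, 1))
  expect_equal(aln$strand, c("+", "-"))
  expect_equal(aln$start, c(101, 301))
  expect_equal(aln$end, c(130, 330))

  aln2 <- align_reads(
    Biostrings::DNAStringSet(c(x = r_twice)), genome2
  )
  expect_equal(aln2$n_placements, 2)

  # oracle agreement on a batch of random reads, some mutated
  for (i in 1:10) {
    p <- sample(1:(600 - 30), 1)
    s <- substr(gstr, p, p + 29)
    if (i %% 2 == 0) {
      pos <- sample(30, 1)
      old <- substr(s, pos, pos)
      substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    got <- align_reads(Biostrings::DNAStringSet(c(r = s)), genome)
    want <- oracle_scan_read(s, gstr)
    if (want$n_exact > 0) {
      expect_equal(got$n_mismatches, 0)
      expect_equal(got$n_placements, want$n_exact)
    } else {
      expect_equal(got$n_mismatches, want$best)
    }
  }

  expect_error(align_reads(reads, Biostrings::DNAStringSet()), "empty")
})

test_that("read_alignments maps SAM fields and skip rules", {
  set.seed(22)
  seq30 <- paste(
    sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""
  )
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, c(
    sam_record("r1", 0, 101, 60, seq30, nm = 0),
    sam_record("r2", 0, 201, 60, seq30, nm = 2),
    sam_record("r3", 0, 301, 60, seq30, nm = 0),
    sam_record("r3", 256, 401, 0, seq30, nm = 0),
    sam_record("r4", 0, 501, 0, seq30, nm = 0),
    sam_record("r5", 0, 601, 60, seq30),         # no NM tag
    sam_record("r6", 4, 0, 0, seq30, rname = "*")  # unmapped
  ))
  aln <- read_alignments(sam)
  expect_equal(nrow(aln), 5) # secondary + unmapped records not rows
  expect_equal(attr(aln, "n_unmapped"), 1)
  expect_equal(attr(aln, "n_missing_nm"), 1)
  r1 <- aln[aln$read_id == "r1", ]
  expect_equal(r1$start, 101)
  expect_equal(r1$end, 130)
  expect_equal(r1$n_mismatches, 0)
  expect_equal(r1$n_placements, 1)
  # primary with a secondary sibling is multi-placed
  expect_gte(aln$n_placements[aln$read_id == "r3"], 2)
  # zero MAPQ is multi-placed
  expect_gte(aln$n_placements[aln$read_id == "r4"], 2)
  expect_true(is.na(aln$n_mismatches[aln$read_id == "r5"]))

  filtered <- filter_alignments(aln)
  expect_equal(filtered$read_id, "r1")
  stats <- attr(filtered, "filter_stats")
  expect_equal(unname(stats["retained"]), 1)
  expect_equal(unname(stats["discarded_mismatch"]), 1)
  expect_equal(unname(stats["discarded_multimapped"]), 2)
  expect_equal(unname(stats["discarded_unknown_nm"]), 1)
})

test_that("the strict filter keeps exactly unique zero-mismatch reads", {
  aln <- data.frame(
    read_id = c("a", "b", "c", "d"),
    chrom = "chr1", start = c(1, 10, 20, 30), end = c(5, 14, 24, 34),
    strand = "+",
    n_mismatches = c(0, 1, 0, NA),
    n_placements = c(1, 1, 2, 1),
    stringsAsFactors = FALSE
  )
  kept <- filter_alignments(aln)
  expect_equal(kept$read_id, "a")
  expect_equal(nrow(filter_alignments(aln[0, ])), 0)
})

test_that("collapse_to_sites groups by junction with strand convention", {
  aln <- data.frame(
    read_id = sprintf("r%d", 1:5),
    chrom = "chr1",
    start = c(100, 100, 100, 200, 200),
    end = c(129, 129, 129, 229, 229),
    strand = c("+", "+", "+", "-", "-"),
    n_mismatches = 0, n_placements = 1,
    stringsAsFactors = FALSE
  )
  sites <- collapse_to_sites(aln)
  expect_equal(nrow(sites), 2)
  # plus-strand junction at the leftmost, minus-strand at the rightmost
  expect_equal(sites$position, c(100, 229))
  expect_equal(sites$read_count, c(3, 2))
  expect_equal(sum(sites$read_count), nrow(aln))
  expect_equal(nrow(collapse_to_sites(aln[0, ])), 0)
})

test_that("a gene with the screen's headline counts summarizes exactly", {
  counts <- c(9384L, 56450L, 404817L, 12L, 7L, 3L)
  aln <- data.frame(
    read_id = sprintf("r%d", seq_len(sum(counts))),
    chrom = "chr1",
    start = rep(seq(100, by = 50, length.out = 6), counts),
    end = rep(seq(129, by = 50, length.out = 6), counts),
    strand = "+", n_mismatches = 0, n_placements = 1,
    stringsAsFactors = FALSE
  )
  sites <- collapse_to_sites(aln)
  expect_equal(nrow(sites), 6)
  expect_equal(sort(sites$read_count), sort(counts))
  expect_equal(sum(sites$read_count), 470673L)
})

test_that("annotate_orientation applies the sense rule and overlaps", {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 450), c(499, 700)),
    strand = c("+", "-"),
    gene_id = c("geneA", "geneB")
  )
  sites <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    position = c(200, 200, 600, 901, 5),
    strand = c("+", "-", "-", "+", "+"),
    read_count = 1L,
    stringsAsFactors = FALSE
  )[c(1, 2, 3, 4, 5), ]
  # duplicate strands: make rows distinct sites
  sites$position[2] <- 210
  ann <- annotate_orientation(sites, genes)
  a200 <- ann[ann$position == 200, ]
  expect_equal(a200$gene_id, "geneA")
  expect_equal(a200$orientation, "sense")
  a210 <- ann[ann$position == 210, ]
  expect_equal(a210$orientation, "antisense")
  a600 <- ann[ann$position == 600, ]
  expect_equal(a600$gene_id, "geneB")
  expect_equal(a600$orientation, "sense") # minus site in minus gene
  expect_equal(ann$orientation[ann$position == 901], "intergenic")
  expect_equal(ann$gene_id[ann$position == 901], "")
  expect_equal(ann$orientation[ann$chrom == "chr2"], "intergenic")
  expect_equal(attr(ann, "n_unknown_chrom"), 1)

  # a site inside two overlapping genes yields one record per gene
  s_ov <- data.frame(
    chrom = "chr1", position = 470, strand = "+", read_count = 2L,
    stringsAsFactors = FALSE
  )
  ann_ov <- annotate_orientation(s_ov, genes)
  expect_equal(nrow(ann_ov), 2)
  expect_setequal(ann_ov$gene_id, c("geneA", "geneB"))
  expect_setequal(ann_ov$orientation, c("sense", "antisense"))
  # invariant to listing order of the genes
  ann_sw <- annotate_orientation(s_ov, rev(genes))
  reorder <- function(x) {
    x <- x[order(x$gene_id), c("gene_id", "orientation")]
    rownames(x) <- NULL
    x
  }
  expect_equal(reorder(ann_ov), reorder(ann_sw))
})

test_that("zero-mismatch reads round-trip to the simulated site set", {
  cfg <- screen_sim_config(
    genome_length = 8000, n_genes = 5, n_cells = 120,
    n_control_cells = 120, resistance_genes = "gene002",
    readcount_log_mean = 0.5, readcount_log_sd = 0.5,
    p_survive_resistant = 0.9, p_survive_background = 0.3, seed = 31
  )
  scr <- simulate_screen(cfg)
  surv <- scr$selected
  ok <- ifelse(
    surv$strand == "+",
    surv$position + cfg$read_length - 1 <= cfg$genome_length,
    surv$position >= cfg$read_length
  )
  surv <- surv[ok, ]
  truth <- survivor_sites(surv)
  reads <- generate_reads(
    surv, scr$genome, cfg$read_length, 0, seed = 32
  )
  got <- collapse_to_sites(filter_alignments(align_reads(
    reads, scr$genome
  )))
  expect_equal(
    got[c("chrom", "position", "strand")],
    truth[c("chrom", "position", "strand")]
  )
  expect_equal(sum(got$read_count), length(reads))
})
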