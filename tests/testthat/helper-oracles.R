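# Independent oracles and small fixture builders. Each oracle is a
# direct textbook computation, kept free of the package code paths it
# checks.

# one-sided Fisher p for [k1, n1-k1; k2, n2-k2] by explicit summation
# of hypergeometric point probabilities from log-factorials
oracle_fisher_p <- function(k1, n1, k2, n2) {
  draws <- k1 + k2
  jmax <- min(n1, draws)
  j <- k1:jmax
  if (length(j) == 0L) return(0)
  lp <- lchoose(n1, j) + lchoose(n2, draws - j) - lchoose(n1 + n2, draws)
  sum(exp(lp))
}

# Benjamini-Hochberg by the step-up definition: sort ascending, q_i =
# min over j >= i of p_j * n / j, capped at 1, mapped back to input order
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  pmin(q_sorted, 1)[order(o)]
}

# paired t from the textbook formula
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# closed-form OLS on the log10-transformed median-effect pairs
oracle_median_effect <- function(dose, fa) {
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  m <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b <- mean(y) - m * mean(x)
  list(m = m, Dm = 10^(-b / m))
}

# brute-force full-length scan of a read against both genome strands:
# returns exact-placement count and best mismatch count with positions
oracle_scan_read <- function(read, genome_str) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(
    rev(comp[strsplit(read, "")[[1]]]),
    collapse = ""
  )
  g <- strsplit(genome_str, "")[[1]]
  scan1 <- function(seq) {
    s <- strsplit(seq, "")[[1]]
    w <- length(s)
    starts <- seq_len(length(g) - w + 1L)
    vapply(starts, function(p) sum(g[p:(p + w - 1L)] != s), numeric(1))
  }
  mm_f <- scan1(read)
  mm_r <- scan1(rc)
  list(
    n_exact = sum(mm_f == 0) + sum(mm_r == 0),
    best = min(mm_f, mm_r),
    fwd_exact_at = which(mm_f == 0),
    rev_exact_at = which(mm_r == 0)
  )
}

# small annotated-sites fixture mirroring the screen's headline gene:
# one gene with six distinct sense sites (three with very large read
# counts) in a 50-gene background carrying at most `bg_sites` sites each
make_top_gene_fixture <- function(bg_sites = 2L, seed = 42L) {
  set.seed(seed)
  genes <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(
      start = seq(1L, by = 2000L, length.out = 50L), width = 1000L
    ),
    strand = "+",
    gene_id = sprintf("gene%03d", 1:50)
  )
  top_counts <- c(9384L, 56450L, 404817L, 12L, 7L, 3L)
  top <- data.frame(
    chrom = "chr1",
    position = as.integer(seq(100L, by = 100L, length.out = 6L)),
    strand = "+", read_count = top_counts,
    gene_id = "gene001", orientation = "sense",
    stringsAsFactors = FALSE
  )
  bg <- do.call(rbind, lapply(2:50, function(i) {
    k <- sample.int(bg_sites + 1L, 1L) - 1L
    if (k == 0L) return(NULL)
    data.frame(
      chrom = "chr1",
      position = as.integer(
        (i - 1L) * 2000L + sample.int(900L, k)
      ),
      strand = "+",
      read_count = sample.int(50L, k, replace = TRUE),
      gene_id = sprintf("gene%03d", i), orientation = "sense",
      stringsAsFactors = FALSE
    )
  }))
  list(genes = genes, selected = rbind(top, bg))
}

# flat control sites: one sense site per gene
make_flat_control <- function(genes) {
  data.frame(
    chrom = "chr1",
    position = GenomicRanges::start(genes) + 10L,
    strand = "+",
    read_count = 5L,
    gene_id = genes$gene_id,
    orientation = "sense",
    stringsAsFactors = FALSE
  )
}

# fresh scratch directory per test (cleaned up with the R session)
withr_like_tempdir <- function() {
  d <- tempfile("trapscreen-test-")
  dir.create(d)
  d
}

# minimal SAM writer for read_alignments tests
write_test_sam <- function(path, records,
                           sq = "@SQ\tSN:chr1\tLN:5000") {
  writeLines(c("@HD\tVN:1.6\tSO:unknown", sq, records), path)
}

sam_record <- function(qname, flag, pos, mapq, seq,
                       nm = NULL, rname = "chr1",
                       cigar = paste0(nchar(seq), "M")) {
  fields <- c(
    qname, flag, rname, pos, mapq,
    if (flag == 4) "*" else cigar,
    "*", 0, 0, seq, strrep("I", nchar(seq))
  )
  if (!is.null(nm)) fields <- c(fields, paste0("NM:i:", nm))
  paste(fields, collapse = "\t")
}
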