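test_that("summarize_by_gene counts unique sites and reads per gene", {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 1000), c(500, 1500)),
    strand = "+", gene_id = c("geneA", "geneB")
  )
  none <- summarize_by_gene(
    annotate_orientation(
      data.frame(
        chrom = character(0), position = integer(0),
        strand = character(0), read_count = integer(0)
      ), genes
    ),
    genes
  )
  expect_equal(nrow(none), 2)
  expect_true(all(none$unique_sense == 0 & none$reads_total == 0))

  counts <- c(9384L, 56450L, 404817L, 12L, 7L, 3L)
  sites <- data.frame(
    chrom = "chr1",
    position = c(seq(10, by = 50, length.out = 6), 1100, 1200, 1300),
    strand = c(rep("+", 6), "+", "+", "-"),
    read_count = c(counts, 4L, 5L, 6L),
    stringsAsFactors = FALSE
  )
  summ <- summarize_by_gene(annotate_orientation(sites, genes), genes)
  a <- summ[summ$gene_id == "geneA", ]
  expect_equal(a$unique_sense, 6L)
  expect_equal(a$unique_total, 6L)
  expect_equal(a$reads_total, 470673L)
  b <- summ[summ$gene_id == "geneB", ]
  expect_equal(b$unique_sense, 2L) # the minus-strand site is antisense
  expect_equal(b$unique_total, 3L)
  expect_equal(b$reads_sense, 9L)
  expect_equal(b$reads_total, 15L)
})

test_that("one-sided Fisher p matches the hypergeometric oracle", {
  # no signal: all-zero gene
  sel <- data.frame(
    gene_id = c("g1", "g2"), unique_sense = c(0L, 10L),
    unique_total = c(0L, 10L), reads_sense = c(0L, 50L),
    reads_total = c(0L, 50L)
  )
  ctl <- data.frame(
    gene_id = c("g1", "g2"), unique_sense = c(0L, 20L),
    unique_total = c(0L, 20L), reads_sense = c(0L, 60L),
    reads_total = c(0L, 60L)
  )
  res <- fisher_enrichment(sel, ctl)
  expect_equal(res$p_value[res$gene_id == "g1"], 1)

  # the spec's sharp table [5, 95; 0, 1000]
  p <- fisher_enrichment(
    data.frame(
      gene_id = c("g", "rest"), unique_sense = c(5L, 95L),
      unique_total = c(5L, 95L), reads_sense = c(5L, 95L),
      reads_total = c(5L, 95L)
    ),
    data.frame(
      gene_id = c("g", "rest"), unique_sense = c(0L, 1000L),
      unique_total = c(0L, 1000L), reads_sense = c(0L, 1000L),
      reads_total = c(0L, 1000L)
    )
  )
  p_g <- p$p_value[p$gene_id == "g"]
  expect_equal(p_g, oracle_fisher_p(5, 100, 0, 1000), tolerance = 1e-12)
  # cross-check against fisher.test as a second independent route
  expect_equal(
    p_g,
    fisher.test(
      matrix(c(5, 95, 0, 1000), 2, byrow = TRUE),
      alternative = "greater"
    )$p.value,
    tolerance = 1e-10
  )

  # random tables against both oracles
  set.seed(7)
  for (i in 1:50) {
    n1 <- sample(1:40, 1)
    n2 <- sample(1:40, 1)
    k1 <- sample(0:n1, 1)
    k2 <- sample(0:n2, 1)
    got <- trapscreen:::fisher_p_greater(k1, n1, k2, n2)
    expect_equal(got, oracle_fisher_p(k1, n1, k2, n2),
                 tolerance = 1e-12)
  }

  # monotonicity: more selected-arm hits never raises the p-value
  ps <- trapscreen:::fisher_p_greater(0:20, 30, 5, 40)
  expect_true(all(diff(ps) <= 1e-15))

  expect_error(
    fisher_enrichment(sel, transform(ctl, unique_sense = 0L)),
    "control"
  )
})

test_that("odds ratio uses the sample form with infinities allowed", {
  sel <- data.frame(
    gene_id = c("g", "rest"), unique_sense = c(5L, 5L),
    unique_total = c(5L, 5L), reads_sense = c(5L, 5L),
    reads_total = c(5L, 5L)
  )
  ctl <- data.frame(
    gene_id = c("g", "rest"), unique_sense = c(2L, 18L),
    unique_total = c(2L, 18L), reads_sense = c(2L, 18L),
    reads_total = c(2L, 18L)
  )
  res <- fisher_enrichment(sel, ctl)
  expect_equal(
    res$odds_ratio[res$gene_id == "g"], (5 * 18) / (5 * 2)
  )
  ctl0 <- transform(ctl, unique_sense = c(0L, 20L))
  expect_equal(
    fisher_enrichment(sel, ctl0)$odds_ratio[1], Inf
  )
})

test_that("bh_adjust matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(
    bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4)
  )
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(8)
  for (i in 1:5) {
    p <- runif(200)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("dual ranking applies the tie-break rules, order-invariantly", {
  mk <- function(ids, uniq, reads) {
    data.frame(
      gene_id = ids, unique_sense = uniq, unique_total = uniq,
      reads_sense = reads, reads_total = reads,
      k_sel = uniq, n_sel = sum(uniq), k_ctl = 1L,
      n_ctl = length(ids),
      odds_ratio = 1, p_value = runif(length(ids)),
      stringsAsFactors = FALSE
    )
  }
  single <- rank_genes(mk("only", 3L, 10L))
  expect_equal(single$rank_unique, 1L)
  expect_equal(single$rank_total, 1L)

  set.seed(9)
  res <- mk(c("geneA", "geneB", "geneC"),
            c(6L, 6L, 2L), c(470673L, 100L, 999L))
  ranked <- rank_genes(res)
  expect_equal(
    ranked$gene_id[order(ranked$rank_unique)],
    c("geneA", "geneB", "geneC") # A before B via reads tie-break
  )
  expect_equal(
    ranked$gene_id[order(ranked$rank_total)],
    c("geneA", "geneC", "geneB")
  )
  # permuting input order leaves ranks unchanged
  perm <- rank_genes(res[c(3, 1, 2), ])
  expect_equal(
    perm[order(perm$gene_id), c("gene_id", "rank_unique", "rank_total")],
    ranked[order(ranked$gene_id),
           c("gene_id", "rank_unique", "rank_total")]
  )
})

test_that("screen_report emits the table and site diagrams", {
  fix <- make_top_gene_fixture()
  ctl <- make_flat_control(fix$genes)
  ranked <- enrich_genes(fix$selected, ctl, fix$genes)
  expect_equal(nrow(ranked), 50)

  rpt <- screen_report(
    ranked, fix$genes, sites = fix$selected,
    diagram_genes = "gene001"
  )
  expect_equal(nrow(rpt$table), 50)
  d <- rpt$diagrams$gene001
  expect_equal(nrow(d), 6)
  # gene001 starts at 1; the first fixture site at 100 is 99 inside
  expect_equal(d$rel_position[d$position == 100], 99)
  expect_error(
    screen_report(ranked, fix$genes, diagram_genes = "nope"),
    "known gene_ids"
  )

  tsv <- tempfile(fileext = ".tsv")
  screen_report(ranked, fix$genes, sites = fix$selected, path = tsv)
  back <- read_tsv_with_meta(tsv)
  expect_equal(nrow(back), 50)
  expect_equal(back$gene_id, ranked$gene_id)
})

test_that("a spiked resistance gene is recovered at the top rank", {
  cfg <- screen_sim_config(
    genome_length = 100000, n_genes = 50, n_cells = 20000,
    n_control_cells = 20000, resistance_genes = "gene007",
    p_survive_resistant = 0.95, p_survive_background = 1e-3,
    seed = 77
  )
  scr <- simulate_screen(cfg)
  sel <- annotate_orientation(survivor_sites(scr$selected), scr$genes)
  ctl <- annotate_orientation(survivor_sites(scr$control), scr$genes)
  ranked <- enrich_genes(sel, ctl, scr$genes)
  top <- ranked[ranked$rank_unique == 1, ]
  expect_equal(top$gene_id, "gene007")
  expect_equal(top$q_value, min(ranked$q_value))
  expect_lt(top$p_value, 1e-4)
})
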