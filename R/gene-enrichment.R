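#' Summarize annotated insertion sites per gene
#'
#' Counts, for every gene in the gene set (zero counts allowed), the
#' distinct sense-orientation sites (`unique_sense` — the inactivating
#' insertions), distinct sites of any orientation (`unique_total`), and
#' the corresponding summed read counts (`reads_sense`, `reads_total`).
#' Unique-site counts and read totals are both reported because read
#' counts are inflated by orders of magnitude through clonal expansion
#' and inverse-PCR skew; intergenic sites are excluded.
#'
#' @param sites annotated site data.frame from [annotate_orientation()].
#' @param genes gene models ([GenomicRanges::GRanges] with `gene_id`)
#'   or a character vector of gene identifiers.
#' @return data.frame with one row per gene: `gene_id`, `unique_sense`,
#'   `unique_total`, `reads_sense`, `reads_total`.
#' @export
summarize_by_gene <- function(sites, genes) {
  gene_ids <- if (is.character(genes)) genes else genes$gene_id
  out <- data.frame(
    gene_id = gene_ids,
    unique_sense = 0L, unique_total = 0L,
    reads_sense = 0L, reads_total = 0L,
    stringsAsFactors = FALSE
  )
  genic <- sites[sites$orientation != "intergenic", , drop = FALSE]
  if (nrow(genic) > 0L) {
    sense <- genic[genic$orientation == "sense", , drop = FALSE]
    tab <- function(df, f) {
      x <- tapply(df$read_count, df$gene_id, f)
      x[match(gene_ids, names(x))]
    }
    cnt <- function(df) {
      x <- table(df$gene_id)
      as.integer(x[match(gene_ids, names(x))])
    }
    fill <- function(x) ifelse(is.na(x), 0L, as.integer(x))
    out$unique_total <- fill(cnt(genic))
    out$unique_sense <- fill(cnt(sense))
    out$reads_total <- fill(tab(genic, sum))
    out$reads_sense <- fill(tab(sense, sum))
  }
  out
}

#' One-sided Fisher exact enrichment per gene
#'
#' For each gene, builds the 2x2 table of unique sense-orientation site
#' counts `[k_sel, n_sel - k_sel; k_ctl, n_ctl - k_ctl]`, where `n` is
#' the population-wide total of unique sense sites, and computes the
#' one-sided (enrichment in the selected population) Fisher exact
#' p-value — the hypergeometric upper tail, evaluated exactly. The
#' counting unit is distinct sites, not reads: read counts are
#' PCR/expansion-inflated. The odds ratio is the sample odds ratio with
#' infinities allowed (0/0 yields NaN).
#'
#' @param selected,control per-gene summaries from
#'   [summarize_by_gene()] for the selected and control populations
#'   (matched by `gene_id`; genes absent from one side count 0 there).
#' @return data.frame per gene with the selected-arm summary columns
#'   plus `k_sel`, `n_sel`, `k_ctl`, `n_ctl`, `odds_ratio`, `p_value`.
#' @export
fisher_enrichment <- function(selected, control) {
  n_sel <- sum(selected$unique_sense)
  n_ctl <- sum(control$unique_sense)
  if (n_sel == 0L) stop("selected population has no sense sites")
  if (n_ctl == 0L) stop("control population has no sense sites")
  gene_ids <- union(selected$gene_id, control$gene_id)
  k_sel <- selected$unique_sense[match(gene_ids, selected$gene_id)]
  k_sel[is.na(k_sel)] <- 0L
  k_ctl <- control$unique_sense[match(gene_ids, control$gene_id)]
  k_ctl[is.na(k_ctl)] <- 0L
  out <- selected[match(gene_ids, selected$gene_id), , drop = FALSE]
  out$gene_id <- gene_ids
  zero <- is.na(out$unique_sense)
  out[zero, c("unique_sense", "unique_total",
              "reads_sense", "reads_total")] <- 0L
  out$k_sel <- k_sel
  out$n_sel <- n_sel
  out$k_ctl <- k_ctl
  out$n_ctl <- n_ctl
  out$odds_ratio <- (k_sel * (n_ctl - k_ctl)) /
    ((n_sel - k_sel) * k_ctl)
  out$p_value <- fisher_p_greater(k_sel, n_sel, k_ctl, n_ctl)
  rownames(out) <- NULL
  out
}

# one-sided Fisher exact p for table [k1, n1-k1; k2, n2-k2]:
# P(X >= k1), X ~ Hypergeometric with k1+k2 draws of the first column
# from n1 "selected" and n2 "control" sites; vectorized
fisher_p_greater <- function(k1, n1, k2, n2) {
  phyper(k1 - 1, n1, n2, k1 + k2, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment at the gene level.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("all p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Rank genes by unique and total insertions
#'
#' The screen's dual ranking: `rank_unique` orders genes by the number
#' of unique sense insertions (descending), `rank_total` by the total
#' read count over all insertions (descending). Ties are broken by the
#' other count (descending), then by `gene_id` (ascending), so ranks
#' are a permutation of `1..n_genes` and invariant to input order.
#' q-values are filled from the enrichment p-values via [bh_adjust()].
#'
#' @param results data.frame from [fisher_enrichment()].
#' @return `results` with `q_value`, `rank_unique` and `rank_total`
#'   columns, sorted by `rank_unique`.
#' @export
rank_genes <- function(results) {
  if (nrow(results) == 0L) {
    results$q_value <- numeric(0)
    results$rank_unique <- integer(0)
    results$rank_total <- integer(0)
    return(results)
  }
  results$q_value <- bh_adjust(results$p_value)
  ord_u <- order(
    -results$unique_sense, -results$reads_total, results$gene_id
  )
  ord_t <- order(
    -results$reads_total, -results$unique_sense, results$gene_id
  )
  results$rank_unique[ord_u] <- seq_len(nrow(results))
  results$rank_total[ord_t] <- seq_len(nrow(results))
  out <- results[order(results$rank_unique), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ranked screen report with per-gene insertion diagrams
#'
#' Emits the ranked enrichment table and, for each requested gene, the
#' unique insertion-site positions relative to the gene start — the
#' data behind a site diagram drawing each insertion as a tick along
#' the gene body.
#'
#' @param results ranked data.frame from [rank_genes()].
#' @param genes gene models ([GenomicRanges::GRanges] with `gene_id`).
#' @param sites annotated selected-arm sites (needed for diagrams).
#' @param diagram_genes character vector of gene ids to diagram.
#' @param path optional output path for the ranked TSV.
#' @return list with `table` (the ranked report) and `diagrams` (a
#'   named list of data.frames with `position`, `rel_position`,
#'   `strand`, `orientation`, `read_count`).
#' @export
screen_report <- function(results, genes, sites = NULL,
                          diagram_genes = character(0), path = NULL) {
  known <- genes$gene_id
  bad <- setdiff(diagram_genes, known)
  if (length(bad) > 0L) {
    stop(
      "unknown gene(s): ", paste(bad, collapse = ", "),
      "; known gene_ids: ", paste(known, collapse = ", ")
    )
  }
  diagrams <- setNames(
    lapply(diagram_genes, function(g) {
      if (is.null(sites)) stop("`sites` required for diagrams")
      gs <- sites[sites$gene_id == g, , drop = FALSE]
      gstart <- GenomicRanges::start(genes)[match(g, known)]
      data.frame(
        position = gs$position,
        rel_position = gs$position - gstart,
        strand = gs$strand,
        orientation = gs$orientation,
        read_count = gs$read_count,
        stringsAsFactors = FALSE
      )
    }),
    diagram_genes
  )
  if (!is.null(path)) {
    write_tsv_with_meta(results, path)
  }
  list(table = results, diagrams = diagrams)
}

#' Full enrichment analysis from annotated sites
#'
#' Composition of [summarize_by_gene()], [fisher_enrichment()],
#' [bh_adjust()] and [rank_genes()] for a selected/control pair of
#' annotated site tables.
#'
#' @param selected_sites,control_sites annotated site data.frames.
#' @param genes gene models ([GenomicRanges::GRanges] with `gene_id`).
#' @return ranked enrichment data.frame (see [rank_genes()]).
#' @export
enrich_genes <- function(selected_sites, control_sites, genes) {
  rank_genes(fisher_enrichment(
    summarize_by_gene(selected_sites, genes),
    summarize_by_gene(control_sites, genes)
  ))
}
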