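#' Run the full screen pipeline: map both arms, rank genes
#'
#' Executes insertion mapping on the selected and control read sets
#' (FASTQ against a reference, or pre-aligned SAM), then the per-gene
#' enrichment and dual ranking. Any stage error aborts the run naming
#' the stage, with partial outputs removed. When `out_prefix` is given,
#' the stage outputs are written as metadata-carrying TSVs
#' (`<prefix>_selected_sites.tsv`, `<prefix>_control_sites.tsv`,
#' `<prefix>_ranked_genes.tsv`) plus a run manifest
#' (`<prefix>_manifest.tsv`) recording package version, seed,
#' parameters and per-stage record counts.
#'
#' @param selected,control inputs for each arm: a FASTQ path or
#'   [Biostrings::DNAStringSet] (used with `genome`), or a list
#'   `list(sam = path)` for external alignments.
#' @param genome reference FASTA path or [Biostrings::DNAStringSet].
#' @param genes gene models (GRanges with `gene_id`, or GTF/BED path).
#' @param out_prefix optional output path prefix.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed documents upstream simulation runs).
#' @return list with `selected_sites`, `control_sites`, `ranked`
#'   (the ranked enrichment table) and `manifest`.
#' @export
run_screen_pipeline <- function(selected, control, genome = NULL,
                                genes, out_prefix = NULL, seed = NA) {
  if (is.character(genes)) genes <- read_genes(genes)
  written <- character(0)
  abort_stage <- function(stage, e) {
    unlink(written)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  map_arm <- function(input, arm) {
    tryCatch({
      if (is.list(input) && !is.null(input$sam)) {
        map_insertions(sam = input$sam, genes = genes)
      } else {
        if (is.character(input) && !file.exists(input)) {
          stop("missing input file: ", input)
        }
        map_insertions(reads = input, genome = genome, genes = genes)
      }
    }, error = function(e) abort_stage(paste0("map-", arm), e))
  }
  sel_sites <- map_arm(selected, "selected")
  ctl_sites <- map_arm(control, "control")
  ranked <- tryCatch(
    enrich_genes(sel_sites, ctl_sites, genes),
    error = function(e) abort_stage("rank-genes", e)
  )
  manifest <- data.frame(
    key = c(
      "package_version", "seed", "n_genes",
      "selected_sites", "control_sites",
      "selected_reads_retained", "control_reads_retained"
    ),
    value = as.character(c(
      as.character(packageVersion("trapscreen")), seed, length(genes),
      nrow(sel_sites), nrow(ctl_sites),
      attr(sel_sites, "filter_stats")[["retained"]] %||% NA,
      attr(ctl_sites, "filter_stats")[["retained"]] %||% NA
    )),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_prefix)) {
    meta <- list(seed = seed)
    paths <- paste0(
      out_prefix,
      c("_selected_sites.tsv", "_control_sites.tsv",
        "_ranked_genes.tsv", "_manifest.tsv")
    )
    written <- paths
    write_tsv_with_meta(sel_sites, paths[1], meta)
    write_tsv_with_meta(ctl_sites, paths[2], meta)
    write_tsv_with_meta(ranked, paths[3], meta)
    write_tsv_with_meta(manifest, paths[4], meta)
  }
  list(
    selected_sites = sel_sites, control_sites = ctl_sites,
    ranked = ranked, manifest = manifest
  )
}

#' Run the full synergy pipeline on a plate table
#'
#' Normalizes raw signal (when a `raw_signal` column is present),
#' fits the median-effect model to each single-drug series (rows where
#' the other drug's dose is zero), computes the combination index at
#' each combination point — both on the replicate-mean fraction
#' affected and per replicate — and emits normalized isobologram
#' coordinates. An invalid single-drug fit (non-positive slope) lets
#' the run complete with an empty CI table and a prominent warning.
#'
#' @param plate long-format data.frame with columns `drug1_dose`,
#'   `drug2_dose`, `replicate`, and `raw_signal` or `fa` (or
#'   `percent_viability`).
#' @param fa_min,fa_max usable-effect window for the fits.
#' @param out_prefix optional output path prefix; writes
#'   `<prefix>_fits.tsv`, `<prefix>_ci.tsv`, `<prefix>_isobologram.tsv`
#'   and `<prefix>_manifest.tsv`.
#' @param seed integer recorded in the manifest.
#' @return list with `records`, `fit1`, `fit2`, `ci` (mean-based),
#'   `ci_replicates`, `isobologram`, `manifest`.
#' @export
run_synergy_pipeline <- function(plate, fa_min = 0.005, fa_max = 0.995,
                                 out_prefix = NULL, seed = NA) {
  records <- if (!is.null(plate$raw_signal)) {
    normalize_viability(plate)
  } else if (!is.null(plate$fa)) {
    plate
  } else if (!is.null(plate$percent_viability)) {
    plate$fa <- pmin(pmax(1 - plate$percent_viability / 100, 0), 1)
    plate
  } else {
    stop("plate needs a `raw_signal`, `fa` or `percent_viability` column")
  }
  single1 <- records[
    records$drug2_dose == 0 & records$drug1_dose > 0, , drop = FALSE
  ]
  single2 <- records[
    records$drug1_dose == 0 & records$drug2_dose > 0, , drop = FALSE
  ]
  fit1 <- fit_median_effect(
    single1$drug1_dose, single1$fa, fa_min = fa_min, fa_max = fa_max
  )
  fit2 <- fit_median_effect(
    single2$drug2_dose, single2$fa, fa_min = fa_min, fa_max = fa_max
  )
  combo <- records[
    records$drug1_dose > 0 & records$drug2_dose > 0, , drop = FALSE
  ]
  empty_ci <- combination_index(
    list(m = 1, Dm = 1, valid = TRUE), list(m = 1, Dm = 1, valid = TRUE),
    numeric(0), numeric(0), numeric(0)
  )
  if (!fit1$valid || !fit2$valid) {
    warning(
      "invalid median-effect fit for drug ",
      paste(which(!c(fit1$valid, fit2$valid)), collapse = " and "),
      ": combination-index table left empty"
    )
    ci <- empty_ci
    ci_rep <- empty_ci
  } else if (nrow(combo) == 0L) {
    ci <- empty_ci
    ci_rep <- empty_ci
  } else {
    mean_fa <- summarize_replicates(
      combo, "fa", c("drug1_dose", "drug2_dose")
    )
    usable <- mean_fa$mean > 0 & mean_fa$mean < 1
    mean_fa <- mean_fa[usable, , drop = FALSE]
    ci <- combination_index(
      fit1, fit2, mean_fa$drug1_dose, mean_fa$drug2_dose, mean_fa$mean
    )
    rep_ok <- combo$fa > 0 & combo$fa < 1
    ci_rep <- combination_index(
      fit1, fit2, combo$drug1_dose[rep_ok], combo$drug2_dose[rep_ok],
      combo$fa[rep_ok]
    )
    ci_rep$replicate <- combo$replicate[rep_ok]
  }
  iso <- normalized_isobologram(ci)
  fits <- data.frame(
    drug = c("drug1", "drug2"),
    m = c(fit1$m, fit2$m),
    Dm = c(fit1$Dm, fit2$Dm),
    r = c(fit1$r, fit2$r),
    n_points = c(fit1$n_points, fit2$n_points),
    valid = c(fit1$valid, fit2$valid),
    stringsAsFactors = FALSE
  )
  manifest <- data.frame(
    key = c("package_version", "seed", "n_records",
            "n_combination_points", "fits_valid"),
    value = as.character(c(
      as.character(packageVersion("trapscreen")), seed, nrow(records),
      nrow(ci), fit1$valid && fit2$valid
    )),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_prefix)) {
    meta <- list(seed = seed)
    write_tsv_with_meta(fits, paste0(out_prefix, "_fits.tsv"), meta)
    write_tsv_with_meta(ci, paste0(out_prefix, "_ci.tsv"), meta)
    write_tsv_with_meta(
      iso, paste0(out_prefix, "_isobologram.tsv"), meta
    )
    write_tsv_with_meta(
      manifest, paste0(out_prefix, "_manifest.tsv"), meta
    )
  }
  list(
    records = records, fit1 = fit1, fit2 = fit2,
    ci = ci, ci_replicates = ci_rep, isobologram = iso,
    manifest = manifest
  )
}
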