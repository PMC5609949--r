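---
title: "Methods: gene-trap screen enrichment and median-effect synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-trap screen enrichment and median-effect synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapscreen)
```

## The two analyses

trapscreen implements two computations that together identify a drug
resistance gene and quantify a drug-drug interaction.

**Screen arm.** In a near-haploid cell line (haploid for all
chromosomes but one), a gene-trap retrovirus inserted in the *sense*
orientation inside a gene truncates its transcript — a single
integration suffices for a loss-of-function allele. After mutagenizing
a large pool and applying lethal drug selection, insertions that
inactivate genes required for drug action are enriched among
survivors. Inverse PCR yields reads that begin at the LTR-genome
junction; the analysis maps them back to insertion sites and asks, per
gene, whether the selected population carries more distinct
inactivating insertions than the unselected mutagenized control.

**Synergy arm.** The median-effect model relates dose to fraction
affected: `fa / (1 - fa) = (D / Dm)^m`, with `Dm` the dose giving 50%
effect and `m` the sigmoidicity. For a combination `(d1, d2)`
producing effect `fa`, the combination index in the mutually exclusive
form is `CI = d1/Dx1 + d2/Dx2` with `Dx_i = Dm_i (fa/(1-fa))^(1/m_i)`
the single-drug dose giving the same effect; `CI < 1` is synergy,
`CI = 1` additivity, `CI > 1` antagonism.

## Read filtering, junctions and orientation

The screen's read-level rule is strict: an alignment is used only if
it is unique (exactly one best placement) and has zero mismatches.
`filter_alignments()` applies the rule to alignments from the built-in
exact matcher (`align_reads()`) or from any external aligner via SAM
(`read_alignments()`). For SAM input, mismatches come from the NM tag;
records without NM are *discarded*, not assumed perfect — unknown is
not zero — and uniqueness is approximated as positive mapping quality
with no secondary record for the read, which is the closest statement
of "aligned uniquely" available from a SAM stream.

Junction convention: inverse-PCR reads start at the junction, so for a
plus-strand read the junction base is the leftmost aligned base and
for a minus-strand read the rightmost. `collapse_to_sites()` groups
filtered reads by `(chrom, junction, strand)`: each group is one
unique insertion site whose read count is the group size.

Coordinates are 1-based inclusive throughout, the native convention of
the GenomicRanges containers the package is built on; BED input/output
(0-based half-open) and GTF (1-based inclusive) are converted at the
boundary by rtracklayer. An insertion "position" is the 1-based
coordinate of the first genomic base 3' of the junction.

Orientation uses the full gene body, introns included: gene traps act
intronically, so exon structure is irrelevant to the sense/antisense
call. A site inside several overlapping genes is reported once per
gene rather than silently assigned to one of them.

## Enrichment test and ranking

The test statistic was an open design choice: the screen literature
reports enrichment of inactivating insertions without fixing a test,
and the established, exactly computable choice for count data of this
shape is the one-sided Fisher exact test on distinct sense sites —
`[k_sel, n_sel - k_sel; k_ctl, n_ctl - k_ctl]`, with `n` the
population-wide unique sense-site totals. Distinct sites, not reads,
are the counting unit: read counts at sister sites in the same gene
can differ by four orders of magnitude (the package's worked fixture
uses 9384, 56450 and 404817 against counts of 3-12), purely from
clonal expansion and PCR skew. The p-value is the hypergeometric upper
tail, evaluated exactly and vectorized; the test suite checks it
against an independent enumeration of every 2x2 table with margins up
to 30 at 1e-12. Benjamini-Hochberg correction is applied at the gene
level — unspecified upstream, standard, and reported alongside raw p.
Genes with no insertions in either arm are kept with `p = 1` so the
report schema is stable.

Genes are ranked two ways, as screens of this design report them:
`rank_unique` by distinct sense insertions, `rank_total` by total
reads, each tie-broken by the other count and then by gene identifier,
so ranks are a permutation of `1..n` and invariant to input order.

## The synthetic-data generator

The generator exists so the full arc — genome, mutagenesis, selection,
sequencing, mapping, ranking — runs with controlled ground truth.

* **One insertion per cell**, uniformly placed with a uniform provirus
  strand: the single-copy gene-trap assumption keeps truth
  unambiguous.
* **Selection** is a single per-cell survival probability: high
  (default 0.95) for sense insertions in a designated resistance gene,
  low (default 1e-3) otherwise. Drug kinetics, dosing schedules and
  partial phenotypes are deliberately not modelled.
* **Read counts** per surviving site are log-normal (default
  `meanlog = 3`, `sdlog = 2`), rounded up to at least 1 — a
  heavy-tailed law spanning the observed 4-order-of-magnitude spread
  of insert counts.
* **Reads** are exact genomic flanks 3' of the junction on the
  provirus strand (reverse-complemented for minus-strand insertions),
  with optional per-base substitutions; identifiers encode the true
  site. Default read length is 36 bases, typical of the short-read
  screens this emulates. Sites too close to a sequence end for a
  full-length read are skipped with a warning.
* **Dose-response plates** are drawn from the median-effect equation
  with noise added on the logit scale — the scale on which the model
  is linear — so simulated fractions affected stay strictly inside
  (0, 1). Combination tables solve the Loewe relation
  `d1/Dx1 + d2/Dx2 = 1/interaction` for `fa` (closed form for equal
  slopes, otherwise a bracketed root-find at tolerance 1e-14), so the
  recovered CI equals `1/interaction` by construction.

Default study conditions are a 100 kb toy genome with 50 genes, 2e4
cells per arm and one spiked resistance gene. What passing tests show
is that the pipeline's logic — filtering, collapsing, orientation,
counting, testing, ranking — is correct under its own assumptions.
Real screens add integration-site bias, multi-insertion clones,
mapping ambiguity in repeats, and library-depth asymmetries the
generator does not emulate; the control arm's depth is therefore a
free parameter rather than an assumed ratio.

## Synergy-arm numerics

Viability is normalized as
`100 * (raw - mean blank) / (mean vehicle - mean blank)`; a plate
whose vehicle mean does not exceed its blank mean is rejected as
uninterpretable. `fa = 1 - viability/100` is clipped to `[0, 1]` with
clip events counted (signal above vehicle is apparent stimulation, not
negative kill).

The median-effect fit is ordinary least squares of
`log10(fa/(1-fa))` on `log10(dose)`. Points with `fa <= 0.005` or
`>= 0.995` are excluded before fitting (configurable): the logit
transform diverges at the endpoints and the model is only informative
strictly inside (0, 1). Fewer than two usable points is an error; a
non-positive slope is flagged as an invalid fit and downstream CI
computation refuses it — in the pipeline the run completes with an
empty CI table and a prominent warning. `IC50` is reported as `Dm`
(the `fa = 0.5` identity) rather than refit with a separate sigmoid:
one coherent model.

CI is evaluated at each combination point's own measured effect, with
`fa` averaged across replicates (per-replicate CIs are also emitted
for dispersion); the design uses fixed dose pairs, not a fixed dose
ratio. Interpretation is strictly trichotomous at `CI = 1` — the
numeric CI is always reported so finer bands can be applied
downstream. Normalized isobologram coordinates are
`(d1/Dx1, d2/Dx2)`, whose sum is the CI, so points under the diagonal
are synergistic regardless of effect level. The paired t-test used for
replicate comparisons handles the degenerate zero-variance case by
convention: all-zero differences give `t = 0, p = 1`; constant nonzero
differences give `p = 0`.

## Problem sizes and determinism

Every stochastic operation takes an explicit seed and restores the
caller's RNG state; a single master seed is fanned out to per-stage
seeds by fixed offsets, so one number reproduces a whole run, and
pipeline outputs are byte-identical under rerun. The test suite and
the acceptance script run the screen-recovery property at 100
replicates of 2e4 cells over 50 genes, the mapping round trip at 20
seeds on an 8 kb genome, and the Fisher-vs-enumeration sweep over all
245,025 tables with margins up to 30 — sizes chosen to exercise the
statistics convincingly at desk scale.

## Worked example

```{r example}
cfg <- screen_sim_config(
  genome_length = 50000, n_genes = 20, n_cells = 5000,
  resistance_genes = "gene007", seed = 42
)
scr <- simulate_screen(cfg)
sel <- annotate_orientation(survivor_sites(scr$selected), scr$genes)
ctl <- annotate_orientation(survivor_sites(scr$control), scr$genes)
ranked <- enrich_genes(sel, ctl, scr$genes)
head(ranked[, c("gene_id", "unique_sense", "reads_total",
                "p_value", "q_value", "rank_unique")], 3)
```

```{r synergy}
dr <- simulate_dose_response(dose_response_sim_config(
  m = 1.2, Dm = 0.5, doses = 2^(-4:3), replicates = 3,
  noise_sd = 0.05, seed = 7
))
fit <- fit_median_effect(dr$dose, dr$fa)
fit
combination_index(fit, fit, dose_for_effect(fit, 0.75) / 2,
                  dose_for_effect(fit, 0.75) / 2, 0.75)
```

## Known limitations

The built-in aligner is an exact full-length matcher for desk-scale
genomes — no indels, no quality awareness, no repeat-scale genomes;
large screens should align externally and enter via SAM. The
enrichment model ignores integration-site preference. The synergy arm
implements only the Chou-Talalay median-effect framework (no Bliss,
HSA or ZIP alternatives) and emits coordinates rather than figures.
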