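Package: trapscreen
Title: Haploid Gene-Trap Resistance Screens and Median-Effect Drug Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for haploid gene-trap insertional mutagenesis
    resistance screens: filtering of uniquely aligned zero-mismatch flanking
    reads, collapsing of reads to deduplicated insertion sites, sense-
    orientation annotation against gene models, per-gene enrichment testing
    of a selected population against an unselected mutagenized control
    (one-sided Fisher exact with Benjamini-Hochberg correction), and dual
    ranking of genes by unique and total insertions. A second arm implements
    Chou-Talalay median dose-effect analysis of drug combinations: plate
    viability normalization, median-effect model fits, combination indices
    with synergy calls, normalized isobologram coordinates, and replicate
    statistics. A synthetic-data generator produces toy genomes, mutagenized
    insertion libraries, selection outcomes, junction-flanking reads and
    median-effect dose-response plates with known ground truth, so the full
    analysis arc is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
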