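Package: fragtools
Title: Fragment-Based RNA-Seq Analysis of Two-Sample Embryo Designs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the bespoke computational stages of a
    two-sample (no-replicate) bulk RNA-seq analysis of early embryos:
    polyadenylation-site calling from polyA-tail-bearing reads with an
    internal-priming filter, constitutive-exon digital gene expression with
    exonic/intronic fragment accounting, a negative-binomial exact test for
    differential expression without replicates, intergenic novel
    transcribed-unit discovery with evidence annotation, junction-based
    alternative-splicing detection with Fisher exact differential testing,
    hypergeometric GO enrichment, and a pre-mRNA/intronic-read model.  Includes
    a seeded synthetic-data generator that emulates the study design (3'-biased
    coverage, tunable pre-mRNA fraction, planted polyA sites, novel TUs, and
    differential effects) with complete truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    rtracklayer,
    limma,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
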