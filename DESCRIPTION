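Package: episcan
Title: DNA Methylation Epi-Signature Discovery, Classification and
    Methylation-Array Copy-Number Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for peripheral-blood DNA methylation
    epi-signature analysis of microdeletion syndromes. Provides quality
    control and probe filtering for methylation arrays, reference-based
    blood cell-type deconvolution, moderated per-probe differential
    methylation with empirical-Bayes variance shrinkage, kernel-smoothed
    differentially methylated region (DMR) calling with Stouffer-combined
    false discovery rates, a linear support-vector-machine classifier with
    Platt-scaled methylation variant pathogenicity (MVP) scores, copy-number
    segmentation from summed array intensities with permutation-based change
    points, critical-region mapping by genomic interval arithmetic, and
    rank-based statistics for Biolog phenotype-microarray plates. A
    synthetic-data module generates cohorts with planted signatures,
    deletions and metabolic effects for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    limma,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
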