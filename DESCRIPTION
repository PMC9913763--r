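Package: koSets
Title: Transcription-Factor Dependence Classification from Factorial
    Knockout RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers transcription-factor dependence of genes from a
    factorial knockout RNA-seq design (control, two single-deletion
    strains and the double-deletion strain, each untreated or
    oxidative-stress treated). Provides a simplified negative-binomial
    differential-expression engine (median-of-ratios normalization,
    method-of-moments dispersion, Wald tests with an optional batch
    term), the 27-gene-set algebra that classifies every gene into
    dependence categories (AA, BB, AB, A/B, A-B1 to A-B5), Fisher's
    exact gene-group enrichment, condition summaries and cross-condition
    overlaps, and a synthetic-data generator with known per-gene ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    edgeR,
    fgsea,
    GenomicRanges,
    rtracklayer,
    optparse,
    yaml,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, GeneSetEnrichment,
    RNASeq, Software
RoxygenNote: 7.3.3
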