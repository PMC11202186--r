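Package: cfTSS
Title: TSS Relative Coverage Profiling of Plasma Cell-Free DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers chromatin accessibility from low-pass whole-genome
    sequencing of plasma cell-free DNA by computing relative fragment
    coverage at transcription start sites (TSS), and turns those profiles
    into liquid-biopsy classifiers. Provides training-cohort-frozen z-score
    normalization, stage-monotone feature selection, pathway activity
    ("path") scores from gene sets, stratified cohort splitting, and
    random-forest models with repeated cross-validation and ROC evaluation.
    A seedable synthetic cfDNA cohort generator with planted class, stage
    and pathway structure makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Rsamtools,
    data.table,
    caret,
    fgsea,
    randomForest,
    pROC,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
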