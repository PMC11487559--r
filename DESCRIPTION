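Package: TStateScore
Title: Rank-Based Scoring of T Cell Functional States from Bulk Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies eight T cell functional states (Quiescence, Regulating,
    Proliferation, Helper, Cytotoxicity, Progenitor exhaustion, Terminal
    exhaustion, Senescence) in individual bulk or pseudo-bulk RNA-seq samples.
    Each state is scored by a Mann-Whitney U statistic comparing the within-
    sample expression ranks of a state-specific marker gene set against an
    expression-stratified random background, after log2(TPM+1) transformation
    and housekeeping-gene normalization; scores are then capped marker-wise by
    a single-cell derived reference spectrum so that extreme expression of a
    single marker cannot dominate. Includes pseudo-bulk construction from
    labelled single-cell matrices, a reference-spectrum builder, a synthetic
    cohort generator with planted state effects for validation, and ROC/AUC,
    dominant-state and rank-sum evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC
biocViews: Transcriptomics, GeneExpression, ImmunoOncology, SingleCell,
    GeneSetEnrichment, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
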