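Package: emtGPS
Title: Rank-Based Gene-Pair Signatures for Single-Sample EMT Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers and applies qualitative, within-sample relative
    expression ordering (REO) gene-pair signatures that separate epithelial
    from mesenchymal tumour phenotypes. Mines gene pairs whose ordering is
    stable in epithelial samples and significantly reversed in mesenchymal
    samples (Fisher's exact test), distils them by reversal ratio and
    rank-based differential expression into a compact signature, and scores
    individual samples with an EMT score in [0,1]. Because only the
    within-sample order of expression values is used, discovery and scoring
    are invariant to batch effects and to any monotone normalisation, and a
    single sample can be classified without a reference cohort. Ships the
    published 16-gene-pair ovarian cancer EMT signature, a synthetic-cohort
    generator with planted reversed pairs for validation, ROC/AUC
    evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    SummarizedExperiment,
    pROC,
    survival,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
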