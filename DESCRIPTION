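Package: methboost
Title: Multi-Cell CpG Methylation State Prediction from Sparse Single-Cell Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary CpG methylation states in sparse single-cell
    bisulfite methylomes (scRRBS/scBS-seq) by combining three feature families:
    n-gram frequencies of the 101-bp sequence window around each site,
    binary/score overlaps with genomic annotation tracks (CpG islands, shores,
    shelves, TFBS, chromatin states, histone marks, DHS, iHS, constraint), and
    cross-cell positional features built from the states and distances of
    neighbouring CpG sites within and across cells. A gradient-boosted tree
    classifier is trained per target cell; reference implementations of
    gradient-based one-side sampling and exclusive feature bundling, a full
    evaluation suite (accuracy, AUC, AUPR, F-score, MCC, sensitivity,
    specificity), skip-k neighbourhood analyses, and a synthetic sparse
    methylome simulator make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
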