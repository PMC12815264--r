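Package: hgtcooc
Title: Horizontal Gene Transfer and Co-Occurrence Analysis for Marine
    Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline linking horizontal gene transfer (HGT)
    between prokaryotic genomes to their co-occurrence across metagenomic
    samples, phylogenetic distance, and environment. Includes a synthetic
    data generator with planted ground truth (taxonomy-consistent
    phylogenies, vertically diverged gene families, planted transfer
    events, niche-driven co-occurrence, environmental drivers), HGT
    calling by full-length gene clustering with cross-genus reciprocal
    best hits and by seed-and-extend identity-segment matching,
    hypergeometric co-occurrence tests with compositional
    proportionality, logistic-regression association models with ordered
    quantile normalization and variance inflation diagnostics, COG and
    mobile-genetic-element enrichment tests, and random-forest modelling
    of per-sample HGT prevalence with permutation-null variable
    importance, ICE curves and Friedman's H-statistic.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    SummarizedExperiment,
    S4Vectors,
    ranger,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
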