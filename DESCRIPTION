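Package: coexpipe
Title: Time-Course Co-Expression Network Analysis for No-Replicate RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-usable pipeline for short time-course RNA-seq
    experiments without biological replicates: RPKM normalisation,
    differential expression by the Audic-Claverie exact count test with
    Benjamini-Hochberg false discovery rate control, three-way Venn
    partitioning of gene lists, eight-profile expression-trend
    classification with permutation significance, highest-reciprocal-rank
    (HRR) gene co-expression network construction, a from-scratch Markov
    cluster algorithm (MCL) for module detection, hypergeometric term
    enrichment of modules, and small-assay calculations (Livak 2^-ddCt
    relative quantification and hormone-content ratios). A negative-binomial
    synthetic-data generator with planted co-expression modules, planted
    differentially expressed genes and planted annotation enrichment makes
    every stage testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
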