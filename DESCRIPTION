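Package: epirank
Title: Rank Genes by Differential Epigenetic Signal Propagated over
    Enhancer-Promoter Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates between-condition differences of multiple epigenetic
    marks (ChIP-seq style block signal) at promoters and distal
    promoter-interacting regions via differential principal component
    analysis, propagates the resulting element scores through a directed
    enhancer-to-promoter graph with personalized PageRank into one meta-gene
    score per gene, and benchmarks ranked gene lists with an ECDF/AUC
    rank-enrichment statistic plus a degree-preserving rewiring null model.
    Includes a self-contained synthetic epigenome generator with planted
    differential signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
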