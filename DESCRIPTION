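Package: grffl
Title: Regulatory Network and Feed-Forward Loop Analysis of Glucocorticoid
    Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting early glucocorticoid- and LPS-driven
    transcriptional regulation in macrophages: Z-score / ANOVA / k-means
    expression clustering with elbow-based selection of the cluster number,
    Girvan-Newman community detection with network topology statistics,
    incoherent feed-forward loop (I1-FFL) dynamic modelling and least-squares
    fitting of fold-change time courses, transcription-factor binding-site to
    gene association with hypergeometric and chi-squared enrichment
    statistics, and seeded synthetic-data generators emulating the
    statistical structure of the underlying experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    GenomicRanges,
    igraph,
    IRanges,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
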