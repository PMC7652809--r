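Package: scdnet
Title: Embedding-Based Silhouette Community Detection for Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects non-overlapping communities in undirected, optionally
    weighted networks by clustering node embeddings and selecting the number
    of communities with a two-stage (coarse/fine) Silhouette optimization.
    Node embeddings are computed either by closed-form DeepWalk matrix
    factorization (NetMF) or by personalized PageRank vectors obtained via
    power iteration. Ships partition-quality metrics (normalized mutual
    information, adjusted Rand index, weighted modularity), synthetic
    benchmark generators (Lancichinetti-Fortunato-Radicchi graphs and
    stochastic block models with planted ground truth), and a benchmark
    harness with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
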