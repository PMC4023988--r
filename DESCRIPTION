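Package: bicomm
Title: Dual-Projection Community Detection in Bipartite Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community detection for bipartite (two-mode) networks via the
    dual-projection strategy: detect communities separately on the weighted
    one-mode projections of each mode, then match communities across modes by
    maximizing Barber's bipartite modularity. Also implements the baseline
    "combined" strategy that clusters the block off-diagonal meta-matrix of the
    bipartite graph, planted-partition bipartite benchmark generators with
    known ground truth, normalized mutual information scoring, and a
    Monte-Carlo simulation harness comparing the two strategies. Random-walk
    (walktrap) clustering is the detection backend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
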