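Package: ppiscreen
Title: Topology-Based Gene Screening in Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds protein-protein interaction networks from differentially
    expressed gene lists and STRING-style scored edge tables, computes the
    four node-centrality statistics used in topology-based biomarker
    screening (degree, betweenness, closeness, stress) with an in-package
    graph-algorithm core, and applies the hub / bottleneck / hub-bottleneck /
    central-node selection cascade to nominate candidate genes. Includes a
    seeded generator of scale-free test networks with planted central nodes
    so that every pipeline stage can be validated against a known ground
    truth, plus a command-line interface for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
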