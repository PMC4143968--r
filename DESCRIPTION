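Package: brainplex
Title: Correlation-Network Multiplexes and Pathway Crosstalk for
    Brain-State Feature Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Applies genomic-style network analysis to feature-by-time
    recordings of brain activity. Reconstructs relevance networks from
    whole-series correlation (Pearson, Spearman, or shrinkage-regularised
    partial correlation), thresholds them into binary layers with a
    robustness sweep, validates links with permutation and phase-shift
    surrogate nulls, assembles per-state layers into a multiplex network
    over a common node set, and quantifies inter-layer structure through
    ordered-pair link overlap, Jaccard similarity, and per-node degree
    vectors. A companion module extends gene-set over-representation
    analysis to pathway-pair intersections, building networks of pathways
    whose shared (interface) genes carry an excess of differentially
    expressed genes. Includes a synthetic-data generator with planted
    block-correlation structure and planted enrichment so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
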