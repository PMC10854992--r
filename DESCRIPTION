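Package: diffcornet
Title: Differential Co-Expression Network Analysis with Local-FDR Edge
    Selection and Topological Overlap Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-condition differential co-expression network
    analysis of temporal expression data. Per-condition Pearson correlations
    are Fisher z-transformed and compared with a standardized difference
    statistic; significant differential edges are selected by a local false
    discovery rate with an empirical half-normal null; genes are clustered
    into modules by average-linkage hierarchical clustering of the
    topological overlap of the scaled difference matrix; and hub genes are
    ranked by signed intramodular connectivity. Includes count-matrix
    filtering, marker-list intersection, interaction-network merging and
    ego/induced subnetwork extraction, a planted-module synthetic data
    generator with known ground truth, and a configuration-driven pipeline
    with Cytoscape-compatible exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
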