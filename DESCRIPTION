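Package: omicsbrush
Title: Adjacency-Matrix Brushing and Topological Abstraction for
    Multi-Omics Correlation Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A headless workflow for hypothesis generation on multi-omics
    cohorts. Builds a topological abstraction of sample similarity (STAD:
    a graph whose nodes are samples and whose edges connect similar
    samples, chosen so that graph distances reflect the input distances),
    ranks features discriminating a selected sample group with a robust
    median/IQR delta statistic, converts sample-by-feature matrices into
    node-link correlation graphs with a Canberra profile distance, and
    explores the resulting adjacency matrix: hierarchical-clustering
    reordering, dendrogram cutting for sub-tree colouring, edge
    thresholding, and extraction of contiguous brushed regions or
    dendrogram sub-trees as subgraphs. Feature nodes can be annotated
    against a curated disease-association table to flag strongly
    disease-linked yet unreported features. A synthetic two-group cohort
    generator with known ground truth (group-shifted features, block
    correlation structure, multi-omics concatenation) supports validation
    when the original clinical data are restricted.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'delta.R'
    'graph-model.R'
    'matrix-explorer.R'
    'omicsbrush-package.R'
    'render.R'
    'sample-table.R'
    'simulate.R'
    'stad.R'
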