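Package: manifoldtopo
Title: Topology-Guided Diagnostics for Single-Cell Manifold Inference
    under Heterogeneous Observation Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates droplet-based single-cell RNA-seq UMI count data with
    realistic heterogeneous per-cell observation depth (ranked gene-fraction
    models with linear, exponential and combined growth; Poisson and negative
    binomial expected UMI-multiplicity spectra; benchmark cell populations with
    ground-truth state labels), and provides topology-guided diagnostics for
    graph-based manifold inference: a standard log1p/HVG/PCA/kNN/Louvain
    workflow, partition-based graph abstraction (PAGA) connectivity, Betti
    numbers of the thresholded abstraction graph, random-walk hit rates from
    shallowly observed cells to the deeply observed subset, progressive-removal
    curves and subsampling stability protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    irlba,
    RANN,
    uwot,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
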