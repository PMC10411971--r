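Package: cardiocomm
Title: Comparative Single-Cell Analysis of Cardiac Macrophage-Neutrophil
    Crosstalk Under Regenerative and Macrophage-Delayed Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparative single-cell RNA-seq
    analysis of zebrafish cardiac inflammatory cells after cryoinjury, under
    regenerative (PBS) versus macrophage-delayed (clodronate liposome, CL)
    conditions. Provides 10x-style sparse matrix input/output with barcode-level
    quality control, per-cluster pseudobulk aggregation and normalization, a
    nonparametric M-D (log-ratio, absolute-difference) differential-expression
    caller with simulated technical replicates, differential cluster-composition
    analysis with log2 condition ratios, and condition-specific ligand-receptor
    crosstalk network inference with Cytoscape-compatible exports. A
    negative-binomial synthetic-data generator with planted ground truth
    (cluster proportions, condition-enriched genes, condition-specific
    ligand-receptor pairs) makes every stage testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
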