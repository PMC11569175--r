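Package: scmregions
Title: Cell-State Mapping Regions and Microenvironment Analysis for Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the tissue microenvironment in 10x Visium
    spatial transcriptomics data starting from per-spot cell-state abundance
    estimates. Calls single-cell-mapping (SCM) tissue regions by iterative
    non-negative matrix factorization with a component-uniqueness stopping
    rule, derives cross-sample region-specific gene markers by per-sample
    Wilcoxon differential expression followed by one-sided Fisher
    meta-enrichment, annotates region interfaces on the hexagonal spot
    lattice, scores gene signatures with expression-bin-matched control
    genes, and tests ligand-receptor interactions at region interfaces with
    a permutation test. Ships a synthetic Visium-like cohort generator with
    known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
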