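Package: endmakit
Title: Single-Cell Analysis of Transient Endothelial Mesenchymal Activation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable implementation of the computational pipeline
    used to characterise transient endothelial mesenchymal activation (EndMA)
    in time-course single-cell RNA-seq of the infarcted mouse heart: cell
    quality control and log-normalization, density-based calling of
    lineage-tracing reporter-positive cells, marker-gated EndMA
    classification with time-course kinetics, cell-cycle module scoring and
    phase-proportion testing, a zero-inflated bimodal likelihood-ratio test
    for differential expression, Enrichr-style combined-score term
    enrichment, a four-layer ligand-receptor permutation network, and a
    clonal-expansion area statistic for multicolor reporter images. Ships a
    seeded synthetic-data generator with ground-truth labels so every stage
    is exercisable and testable without the original deposited datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
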