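Package: calshape
Title: Kinetic Modelling and Shape-Space Analysis of Calcium Transients in
    Micropatterned Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell calcium imaging of
    geometrically confined cells. Fits a constrained exponential
    rise-decay model to agonist-evoked fluorescence transients using
    grid-initialised bounded nonlinear least squares, compares groups of
    cells in a low-dimensional trajectory shape space (PCA, MANOVA with
    Bonferroni correction, LDA), applies single-cell quality-control
    filters to high-content segmentation object tables, and scores bulk
    tumor expression profiles on an epithelial-mesenchymal axis with
    quintile stratification. A seeded synthetic-data module generates
    model-based transients, object tables with planted QC violations,
    and latent-axis expression matrices for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
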