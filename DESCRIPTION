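Package: thermoquant
Title: Quantification Pipelines for Hyperthermia Sensitization Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image- and table-based quantification pipelines for assays used to
    evaluate thermo-sensitizers: nuclei segmentation of fluorescence microscopy
    fields (rolling-ball background correction, median denoising, adaptive
    thresholding, watershed separation), Fucci2a cell-cycle classification by
    Gaussian-mixture clustering of per-cell red/green intensities, gamma-H2AX /
    53BP1 focus counting and micronucleus detection from z-stacks, phase-contrast
    growth and Annexin V / YOYO-3 apoptosis scoring, clonogenic surviving
    fractions and enhancement ratios, and SILAC proteomics post-processing
    (downshifted-normal imputation, fold-change calling, one-way ANOVA with
    Benjamini-Hochberg correction). A synthetic-data generator paints microscopy
    fields and abundance matrices with full ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    mclust,
    tiff,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
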