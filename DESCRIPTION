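Package: ecmorph
Title: Image-Based Morphological Profiling of Endothelial Cells Under
    Plasma Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for high-content image-based
    morphological profiling of cultured endothelial cell monolayers
    exposed to patient plasma, together with mitochondrial-function
    readouts and clinical cohort statistics. Includes a seeded
    synthetic-data generator (plate layouts, multichannel fluorescence
    fields with ground truth, latent-factor single-cell feature tables,
    extracellular-flux oxygen-consumption traces, cohort tables),
    seeded nucleus/cell segmentation from junction markers,
    per-cell shape, intensity, texture, radial-distribution,
    colocalisation and mitochondrial-morphology features, per-plate
    normalisation, factor analysis with variance-targeted factor
    selection, linear discriminant scoring of treatment arms,
    paired per-factor testing with false-discovery-rate control,
    mito stress test respiration metrics, and exact contingency-table
    statistics for cohort characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
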