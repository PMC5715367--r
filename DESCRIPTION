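Package: phenoplate
Title: Plate-Based Seedling Phenotyping for Abiotic-Stress Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An image-analysis and statistics pipeline for high-throughput
    plate-based phenotyping of Arabidopsis seedlings under abiotic stress
    (high salt, arsenic toxicity, freezing, phosphate limitation).
    Segments seedlings from visible-light and fluorescence plate
    photographs with assay-specific pixel rules, extracts
    morpho-colorimetric features and hue-class colour profiles per
    "digital plant", calls survival/germination/damage states by
    hierarchical clustering of colour profiles, tests each mutant line
    against wild-type (Fisher's exact test or one-way ANOVA) with
    Benjamini-Hochberg false-discovery-rate control, and triages genes
    into evidence categories with a two-part stringent filter. Includes
    a synthetic-plate generator with known ground truth so every stage
    of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    pheatmap,
    jsonlite,
    optparse,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
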