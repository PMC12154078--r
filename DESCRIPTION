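Package: endoquant
Title: Quantitative Imaging and Plate-Assay Analysis for Brain Endothelial Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the quantitative computations used in studies of brain
    microvascular endothelial cell function: oriented-template (Fiberscore-style)
    actin filament detection with skeletonization, length and polarity metrics;
    Fura-2 ratio calcium-transient shape parameterization with inter-parameter
    correlations; scratch-assay wound-width and migration-rate estimation; and
    plate-assay normalizations (viability, ROS per nucleus, adhesion, Transwell
    apparent permeability) with one-way ANOVA and post hoc significance reporting.
    Includes synthetic-data generators with ground truth for every pipeline stage
    and a declarative configuration layer for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
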