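Package: nucmorph
Title: Nuclear Morphometry, Crowding and Peripheral-Enrichment Analysis for
    Fluorescence and Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nuclear size and shape from calibrated 3D fluorescence
    stacks and 2D histology planes: Gaussian smoothing, global thresholding,
    3D/2D connected-component labelling with minimum-size and border filters,
    per-nucleus volume, surface area, cross-sectional area and intensity,
    cytoplasm-by-subtraction, Delaunay-based internuclear distance with a
    size-corrected crowding index, random region-of-interest tiling of large
    planes, long-axis line scans with a peripheral-enrichment fraction,
    Western-blot lane densitometry and cycloheximide-chase decay summaries,
    and a normality-gated parametric/nonparametric group-comparison layer
    (t/ANOVA+Tukey versus Mann-Whitney/Kruskal-Wallis+Dunn). Ships a synthetic
    microscopy generator with exact ellipsoid ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deldir,
    stats,
    tools,
    utils,
    grDevices,
    tiff,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
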