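Package: fibermag
Title: Analysis of Magnetically Aligned Fiber Composites, Cell Orientation,
    and Spheroid Outgrowth Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative image analysis of magnetically aligned
    electrospun fiber segments embedded in 3D hydrogels and of the cells
    cultured within them. Provides closed-form and quadrature magnetostatics
    for the cylindrical magnet pair of a gelation chamber; nematic-tensor
    anisotropy scoring and orientation color maps for fiber architecture;
    skeleton-based fiber length and width measurement with an entanglement
    metric; per-cell orientation statistics (axial histograms, full width at
    half maximum, angular stratification) and Hoechst/PI viability counting;
    and a complete spheroid-outgrowth migration pipeline (body ellipse
    fitting, outgrowth contiguity classification, watershed nucleus
    splitting, migration distances, population heatmaps and rose
    histograms). A synthetic-scene generator with exact ground truth makes
    every stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    pracma,
    stats,
    grDevices,
    utils,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
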