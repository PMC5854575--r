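Package: khgmorph
Title: 3D Morphometry and Spatial Statistics for Keratohyalin Granule Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of keratohyalin granule maturation from
    multi-channel 3D fluorescence microscopy. Provides synthetic volumetric
    phantoms with closed-form ground truth, point-spread-function modelling
    (theoretical and bead-derived) with Richardson-Lucy deconvolution,
    isosurface-based granule segmentation and morphometry (volume, surface
    area, length, sphericity, aspect ratios, size class), nucleus-relative
    and epidermis-height spatial statistics with Pearson colocalization, and
    LAURDAN generalized-polarization quantification of membrane order with
    double-Gaussian population decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    EBImage,
    minpack.lm,
    tibble,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
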