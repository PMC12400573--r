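Package: fishspotr
Title: Learned Image Enhancement and Fixed-Parameter Spot Detection for
    Fluorescence In Situ Hybridization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects diffraction-limited fluorescence in situ hybridization
    (FISH) spots by first transforming raw microscopy images into uniform,
    high signal-to-noise "enhanced" maps with a compact convolutional
    encoder-decoder network trained on Gaussian heatmap targets, then
    calling spots with fixed rules (local maxima or connected components
    with watershed splitting) at a single global threshold. Includes a
    hybrid Dice plus root-mean-square-error training objective, tri-axial
    blending to apply the 2D network to 3D volumes, block-wise chunked
    inference over array stores for images larger than memory, a
    KD-tree-style point matching and F1/localization-error benchmark suite,
    readers and writers for TIFF, Zarr, N5 and NPZ images and CSV spot
    tables, and a parametric simulator of diffraction-limited spot fields
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
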