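Package: fruitfusion
Title: Mature-Fruit Recognition by Dual Color-Feature Wavelet Image Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Segmentation of ripe (red) fruit in canopy images from a low-cost
    RGB camera. Two chromatic feature images are extracted per scene, the
    CIELAB a* (red-green opponent) component computed from chromaticity
    coordinates and the NTSC YIQ in-phase (I) component, and fused at pixel
    level through a multilevel 2-D wavelet decomposition with a range-based
    convex fusion weight. The fused image is segmented by an adaptive
    threshold (the minimum of an iterative intermeans threshold and Otsu's
    threshold) and cleaned by connected-component area filtering. Includes a
    seeded synthetic scene generator emulating illumination-gradient and
    immature-fruit-overlap disturbances, evaluation against ground-truth
    masks, a contrast-experiment driver, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Matrix,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
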