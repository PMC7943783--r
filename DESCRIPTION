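Package: fringecam
Title: Outline Concealment by Protruding Appendages Under Receptor-Noise-Limited Vision
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how thin protruding appendages (such as the fringed
    neoptile feathers of precocial chicks) conceal an object's outline.
    Renders parametric object-plus-appendage scenes, passes them through an
    achromatic receptor-noise-limited (RNL) vision model with spatial-acuity
    blurring and edge-preserving RNL filtering, measures outline detectability
    with Local Edge Intensity Analysis (LEIA) and a high-edge-intensity (HEI)
    pixel statistic, quantifies luminance transition zones, and runs paired
    with/without-appendage comparisons on photographs or seeded synthetic
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
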