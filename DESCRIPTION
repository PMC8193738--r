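Package: osteodisc
Title: Image-Based Finite-Element Analysis of Intervertebral Disc Bulge
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combined experimental/computational pipeline for bone-disc-bone
    (osteodisc) specimens under axial compression. Generates synthetic
    micro-CT and MR-like phantom volumes of a marker-bearing osteodisc,
    tracks fiducial marker centroids across compression steps to quantify
    intervertebral disc surface bulge, builds specimen-specific nonlinear
    finite-element models with Holzapfel-Gasser-Ogden annulus and
    Mooney-Rivlin nucleus constitutive laws and greyscale-mapped bone,
    calibrates tissue compressibility against peak axial loads with a
    bounded trust-region least-squares method, and scores in-vitro versus
    in-silico agreement with Lin's concordance correlation coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    car,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    optparse
Config/testthat/edition: 3
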