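Package: OdontoID
Title: Computer-Vision Identification from Panoramic Dental Radiographs with
    CNN Age-Gated Database Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forensic odontology tooling for matching postmortem panoramic
    dental radiographs (orthopantomograms, OPGs) against a privacy-preserving
    antemortem feature database. Implements deterministic edge-enhancing
    preprocessing (compass Sobel filter bank, averaging filter), a KAZE-family
    nonlinear scale-space keypoint detector with upright real-valued
    descriptors, bidirectional RANSAC-verified descriptor matching with rank-1
    candidate ranking, a convolutional neural network for dental age regression
    trained natively in R, and an age-gated search policy (fixed or expanding
    radius with early stopping) that restricts and orders database comparisons
    by estimated age. A seeded synthetic-radiograph generator provides
    identity-stable, age-coded fixtures for end-to-end evaluation without
    clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
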