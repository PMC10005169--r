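Package: msimon
Title: Contrast-Agent-Free Ischemia Monitoring from Multispectral Laparoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for out-of-distribution based ischemia monitoring with
    snapshot-mosaic multispectral cameras. Implements a camera model for a
    16-band 4x4 mosaic sensor (band integration, demosaicking, RGB
    reconstruction), a Monte-Carlo photon-transport simulator for layered
    tissue, white/dark reference preprocessing, per-patient density
    estimation with ensembles of affine coupling flows scored by the widely
    applicable information criterion (WAIC), a Beer-Lambert oximetry
    baseline, mixed-model variance decomposition of spectral heterogeneity,
    and a synthetic session generator for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    lme4,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
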