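Package: vowrhog
Title: Blurred Palmprint Verification with Structure-Layer WRHOG Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Verification of blurred palmprint region-of-interest images.
    Implements Gaussian defocus blur simulation with a Roberts-gradient
    sharpness measure, Vese-Osher total-variation structure/texture
    decomposition, a rotation-invariant histogram-of-oriented-gradients
    descriptor weighted by per-block differential box-counting fractal
    dimension (WRHOG), normalized cross-correlation matching, and
    FAR/FRR/EER/decidability evaluation. A synthetic ridge-texture
    generator provides labeled palmprint-like databases so the whole
    pipeline runs without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
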