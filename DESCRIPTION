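Package: spasim
Title: Simulation and Quantification of Peripheral Air Spaces in Dynamic
    Ventilation CT Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic sponge-phantom cross-sections with elliptical air
    spaces are generated under uniaxial compression and rendered through
    ultra-high-resolution (UHR), normal-resolution (NR) and near-ideal
    reference imaging models (Gaussian point-spread function fixed by the
    5% modulation transfer frequency, longitudinal motion blur, additive
    Gaussian noise).  The rendered images are quantified by
    moment-preserving (Tsai) binarization with size-gated particle
    counting, by multi-threshold Betti-number curves (peak b0), and by
    full-width-at-half-maximum trough sizing of individual air spaces.
    A random-intercept linear mixed model with cluster-robust (sandwich)
    standard errors compares imaging modes across compression phases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
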