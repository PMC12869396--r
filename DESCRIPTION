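Package: noisyplume
Title: Noise-Enhanced Bayesian Odor-Source Localization from Binary Sensor Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study maximum-a-posteriori localization of a turbulent
    odor source from instantaneous binary detections by a multisensor agent.
    Provides a conical (and isotropic) parametrization of turbulent
    detection-probability fields with fitting and contour geometry, a
    Gaussian-copula generator of independent or spatiotemporally correlated
    binary odor snapshots with exact marginals, grid-search MAP inference
    under four noise mechanisms (proprioceptive, positional, binary flip,
    raw-signal) with error-corrected variants, the detection-pair and
    infinite-sensor asymptotic theory of optimal noise tuning, and a seeded
    scenario runner with mean-squared-error and bias metrics, regional
    aggregation, and condition comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
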