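Package: traitdisp
Title: Trait-Based Community Assembly Tests for Co-Occurring Congeners
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Null-model tests of within-plot trait dispersion (divergence of
    binary chemical-defense profiles, convergence of continuous resource-use
    traits) and among-plot functional turnover (the TAU_st statistic tested
    against log spatial and soil distance with Mantel permutations), plus the
    supporting ordination machinery (z-scoring, iterative VIF elimination,
    correlation-matrix PCA with broken-stick axis retention, axis-trait
    correlation screening) and a synthetic community-assembly generator with
    known ground truth for type-I and power calibration. Data are exchanged as
    plain CSV tables keyed by plot and species identifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
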