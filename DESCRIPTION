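Package: qpia
Title: Quantitative Pathologic Image Analysis and Elastography Staging of
    Venous Thrombi
Version: 0.1.0
Authors@R:
    person("QPIA", "Maintainers", email = "maintainers@qpia.dev",
           role = c("aut", "cre"))
Description: Quantifies the composition of hematoxylin-eosin stained
    thrombus cross-sections by pixel classification into red (red blood
    cells and platelet trabecula), pink (fibrin) and blue (nuclei and
    calcium salt) components with nonlinear red-intensity weighting, and
    stages deep venous thrombi from longitudinal shear-wave elastography
    measurements: piecewise-linear changepoint detection on daily Young's
    modulus series, recanalization reversal detection on composition
    series, and within/between-thrombus heterogeneity metrics. Includes a
    seeded synthetic-data generator (histology-like section images with
    planted ground truth, elasticity and composition day-series, full
    cohorts) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
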