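Package: fasdiet
Title: Diet Estimation from Fatty Acid Signatures with Simulation
    Diagnostics and Permutation Statistics
Version: 0.1.0
Authors@R:
    person("fasdiet", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative fatty acid signature analysis (QFASA) for
    estimating predator diet composition from adipose tissue fatty acid
    signatures against a multi-species prey library.  Provides
    calibration-coefficient correction, Kullback-Leibler distance
    minimization on the simplex, lipid-content conversion from
    fatty-acid-space mixing coefficients to biomass diet proportions,
    prey-on-prey and pseudo-predator simulation diagnostics, distance-based
    permutation MANOVA on diet compositions with chi-square distance and
    Holm adjustment, Spearman trend tests against annual means and sea-ice
    covariates, a unit-checked predator energetics calculator, and a
    seeded synthetic-data generator so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
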