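Package: oscm
Title: Optimal Stomatal Conductance Models for Citrus Leaf Gas Exchange
Version: 0.1.0
Authors@R:
    person("oscm", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coupled leaf gas-exchange modelling built on the
    Farquhar-von Caemmerer-Berry (FvCB) model of C3 photosynthesis and the
    Cowan-Farquhar optimal stomatal regulation hypothesis. Provides FvCB
    kinetics with peaked-Arrhenius temperature corrections, calibration of
    Vcmax25, Jmax25 and Rd25 from A-ci response curves, analytical
    estimation of the marginal water cost of carbon gain (lambda) from gas
    exchange records, coupled solvers that predict intercellular CO2,
    assimilation, stomatal conductance and transpiration from meteorology
    and a prescribed lambda (Rubisco-limited, RuBP-regeneration-limited and
    combined forms), model-evaluation metrics, perturbation sensitivity
    coefficients, and a synthetic-data generator with known ground truth.
    Calibrated defaults describe orchard citrus in a subtropical monsoon
    climate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
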