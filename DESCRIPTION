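Package: brewkin
Title: Kinetic Modelling and Parameter Estimation of Batch Beer Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two dynamic models of isothermal batch beer fermentation -- a
    biomass-based model with Droop-type sugar-threshold kinetics and a carbon
    dioxide-based model with Monod-logistic kinetics -- together with a complete
    parameter-identification workflow: weighted least-squares estimation with
    multi-start simplex search and Levenberg-Marquardt refinement, staged
    fitting recipes for the temperature laws, Fisher-information-based
    uncertainty quantification (Cramer-Rao covariance, coefficients of
    variation, a-posteriori error bars), a numerical local observability and
    identifiability rank test, and a synthetic-data generator emulating a set
    of four reference batch experiments for end-to-end parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    MASS,
    yaml,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
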