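Package: dinadif
Title: Differential Item Functioning Detection for the DINA Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Marginal maximum likelihood estimation of the DINA
    ("deterministic input, noisy AND") cognitive diagnosis model by the
    EM algorithm, with full-information asymptotic covariance matrices of
    the item parameters (cross-product, observed, and sandwich-type
    estimators, plus the item-wise approximation), and six differential
    item functioning (DIF) detection procedures: four Wald tests built on
    the respective covariance estimators, the Mantel-Haenszel test, and
    the logistic regression likelihood-ratio test.  Includes a simulation
    generator for correlated binary attribute profiles and injected DIF,
    and a Monte Carlo harness that aggregates empirical Type I error and
    power across replications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
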