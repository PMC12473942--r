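Package: seedspan
Title: Probit Viability Kinetics and Longevity Modelling for Dry-Stored Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying seed longevity from germination test
    time-series under controlled storage. Fits the probit viability-loss
    model (initial viability Ki, longevity sigma, half-life P50) by
    least squares on probit-transformed germination percentages and by
    binomial probit regression on raw counts, with bootstrap confidence
    intervals. Implements the seed viability equation relating sigma to
    moisture content and temperature, empirical water-sorption-isotherm
    construction and moisture-basis bookkeeping, genus-level association
    of P50 with collection-site climate, and reproducible generators of
    synthetic germination experiments for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
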