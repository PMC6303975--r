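Package: dsrci
Title: Directly Standardized Rates and Confidence Intervals for Sparse
    Event Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes directly standardized rates (DSRs) from
    age-stratified event counts and person-year denominators using the
    2013 European Standard Population (or any user-supplied standard),
    with three confidence-interval estimators: the normal approximation,
    the Dobson weighted-sum-of-Poissons interval and the Tiwari modified
    gamma interval. Includes a Monte Carlo framework for evaluating
    interval coverage under sparse counts: scenario construction
    (linear age structures and rate schedules calibrated to a target
    expected event total), replicated Poisson simulation, exact
    coverage oracles for standard-proportional populations, tail tables
    of observed versus expected totals, and a small-count suppression
    rule for publication of rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
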