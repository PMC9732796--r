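Package: dfuheor
Title: Markov Cost-Utility Modelling and Feasibility Statistics for
    Diabetic Foot Ulcer Recurrence Prevention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for health-economic evaluation of interventions that
    reduce diabetic foot ulcer (DFU) recurrence. Implements a six-state
    Markov cohort model (post-DFU, non-severe DFU, severe DFU, amputation,
    post-amputation, death) with monthly cycles, discounted QALY and cost
    accumulation, ICER and net-monetary-benefit calculation, threshold
    analysis solving for the relative recurrence reduction that attains a
    target ICER, one-way sensitivity analysis with tornado ordering, SINBAD
    ulcer severity scoring, feasibility-cohort summary statistics, a
    Kaplan-Meier restricted-mean ulcer-free-time estimator with bootstrap
    confidence intervals, and a synthetic-data generator (parameter sets,
    patient cohorts, microsimulated patient histories) for testing every
    stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
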