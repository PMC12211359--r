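Package: statincua
Title: Cost-Utility Analysis of Statin-Initiation Risk Thresholds with Markov Cohort Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort modelling for atherosclerotic
    cardiovascular disease (ASCVD) primary prevention with statins. Implements
    an annual-cycle state-transition engine with acute/chronic staging of
    non-fatal events, societal-perspective costing (direct plus human-capital
    indirect costs), QALY accrual with discounting, risk-threshold screening
    strategies for soft and hard ASCVD outcome models, incremental
    cost-effectiveness frontiers with strict and extended dominance, one-way
    and probabilistic sensitivity analysis with acceptability curves, and a
    synthetic-cohort generator that emulates a large Chinese prospective
    cohort so the full pipeline can be exercised without access-restricted
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
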