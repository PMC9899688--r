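Package: longmediate
Title: Natural Direct and Indirect Effects for Longitudinal Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression-based causal mediation analysis for randomized trials
    with a log-scale continuous outcome and longitudinally measured mediators.
    Reduces each patient's mediator trajectory to a cumulative-mean or
    achieved change-from-baseline summary, fits outcome models with
    exposure-mediator interaction, and returns closed-form natural direct,
    natural indirect and total effects (log and geometric-ratio scales) with
    the proportion mediated, for single and joint multiple mediators.
    Includes percentile-bootstrap confidence intervals, endpoint-week and
    subgroup scans, and a synthetic trial-cohort generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
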