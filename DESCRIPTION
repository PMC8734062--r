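Package: seqppv
Title: Bayesian Updating and Sequential Screening-Test Predictive Values
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form Bayesian mathematics for screening tests: positive and
    negative predictive values as functions of disease prevalence, the posterior
    probability of disease after repeated positive tests, the number of
    independent test iterations required to reach a target positive predictive
    value (with ceiling and feasibility handling), the prevalence at which PPV
    and NPV cross, regeneration of reference iteration tables keyed by the log
    positive likelihood ratio, and a Monte-Carlo simulator that validates the
    closed forms and illustrates how within-subject correlation between repeat
    tests erodes the sequential gain. Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
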