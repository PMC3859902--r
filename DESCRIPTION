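Package: qdisc
Title: Q-Learning Models of Instrumental Discrimination Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and model-based analysis of two-alternative
    instrumental discrimination learning. Builds randomized 96-trial
    stimulus-response schedules (8 blocks of 12 trials, 6 contingencies
    presented twice per block), simulates Q-learning agents with a delta-rule
    weight update and softmax choice governed by a learning rate and an
    inverse-gain (exploration) parameter, and recovers those parameters from
    trial-by-trial choice data by grid-search maximum likelihood with a
    McFadden pseudo-R-squared validation against a random responder. Includes
    cohort-level tools: synthetic patient/control cohorts, block-accuracy
    summaries, permutation group contrasts, covariate screens, and
    marginal/partial correlation analysis of regional gray-matter values
    against learning measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    knitr
Config/testthat/edition: 3
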