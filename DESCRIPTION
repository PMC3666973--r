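Package: gazetask
Title: Decoding Viewing Task from Aggregate Eye-Movement Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for decoding a viewer's task
    (reading, pseudo-reading, scene search, scene memorization) from
    aggregate eye-movement features. Provides a seeded generator of
    synthetic fixation/saccade event cohorts with ex-Gaussian fixation
    duration distributions and participant/session random effects;
    preprocessing filters for long fixations, blink-adjacent events and
    completed search trials; four- and eight-feature trial summaries
    including maximum-likelihood and quantile-based ex-Gaussian parameter
    estimation; a Gaussian Naive Bayes classifier with within-session
    leave-one-out and cross-session evaluation; and permutation-based
    significance testing of classification accuracy against an empirical
    null distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    e1071
Config/testthat/edition: 3
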