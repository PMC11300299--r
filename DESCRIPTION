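Package: smnas9
Title: Abbreviated Neonatal Withdrawal Scale Decision Rules and Titration Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and evaluating clinical decision rules on an
    abbreviated 9-element neonatal opioid withdrawal scale (sMNAS-9) that
    reproduce rules written for the full 19-element MOTHER NAS scale (MNAS)
    inside morphine and buprenorphine dose-titration algorithms. Provides the
    instrument encodings and summed scoring, rolling longitudinal score metrics
    (24-hour averages, sums of three consecutive scores, dose timers), a
    configurable rule-based titration engine, Youden-index optimal cutpoint
    selection with a decision-stump cross-check, infant-level train/test
    evaluation with bootstrap confidence intervals, and a synthetic
    longitudinal-cohort generator so every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
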