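Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection in JADER-style
    spontaneous adverse event report databases. Reads the four-table
    DEMO/DRUG/REAC/HIST schema, links and deduplicates cases, applies the
    standard missing-demographics exclusions, and screens drug-event pairs
    with the reporting odds ratio (ROR) and Woolf 95 percent confidence
    intervals, flagging signals when both the ROR and its lower bound exceed
    one. Includes univariate (chi-square, odds ratio) and multivariate
    (logistic regression with Hosmer-Lemeshow goodness of fit) predictor
    analysis within exposed cohorts, time-to-onset binning and outcome
    summaries, and a synthetic report-database generator with planted
    effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
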