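Package: labourflow
Title: Labour Progression Analysis from Sparse Cervical Dilatation Exams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates centimetre-by-centimetre sojourn times and cumulative
    first-stage durations of labour from sparse, interval-censored cervical
    dilatation examinations. Implements three complementary approaches:
    log-normal maximum likelihood on exact and interval-censored durations, a
    progressive continuous-time multistate Markov model fitted by
    matrix-exponential likelihood on panel-observed dilatation, and a
    three-parameter logistic growth nonlinear mixed model with a random
    inflection point for average labour curves. Includes a synthetic cohort
    generator calibrated to published percentile tables, sample-selection
    filters, partograph alert-line utilities, and an oxytocin-augmentation
    sensitivity driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    ggplot2,
    minpack.lm,
    nlme,
    survival,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
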