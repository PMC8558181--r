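Package: tavicea
Title: Markov Cohort Cost-Effectiveness Modelling of Transcatheter Aortic
    Valve Implantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A monthly-cycle Markov cohort model for the cost-effectiveness
    of transcatheter aortic valve implantation (TAVI) against surgical valve
    replacement or medical therapy in intermediate-risk, high-risk and
    inoperable aortic-stenosis patients, from the perspective of a national
    health system.  Health states are NYHA functional classes I-IV with and
    without stroke history, plus death.  The package converts published
    interval event probabilities to per-cycle probabilities, extrapolates
    mortality linearly beyond the observed follow-up, accrues discounted
    costs, life years and quality-adjusted life years, and computes
    incremental cost-effectiveness and cost-utility ratios.  One-way
    (tornado) and probabilistic sensitivity analyses with
    cost-effectiveness acceptability curves are included, together with a
    synthetic-data generator for the NYHA-transition and utility inputs and
    for closed-form verification regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
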