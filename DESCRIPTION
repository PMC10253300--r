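Package: synergybias
Title: Dose-Response Fitting Bias in Drug-Combination Synergy Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses checkerboard drug-combination viability matrices under
    the three classical reference models (Highest Single Agent, Loewe
    additivity, Bliss independence) with four-parameter logistic single-agent
    fits in two regimes: plateaus box-constrained to the 0-100% viability
    range, or with a free lower plateau. Quantifies how the fitting regime
    shifts matrix-level synergy scores and classifications, contrasts the
    plain-mean and significance-weighted scoring conventions, and normalizes
    scores against simulated fully synergistic and fully antagonistic extreme
    matrices. Includes a synthetic checkerboard generator with known ground
    truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
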