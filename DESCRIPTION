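Package: ppdfair
Title: Fairness Audit and Debiasing Pipeline for Postpartum Depression Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pre-implementation evaluation toolkit for a clinical risk
    prediction model of postpartum depression (PPD). Provides seeded synthetic
    electronic-health-record-like delivery cohorts calibrated to published
    dataset profiles, an L2-regularized logistic risk model with per-subject
    weights and input nullification, decision-curve (net benefit) analysis,
    a five-metric group-fairness audit with acceptance ranges (statistical
    parity difference, disparate impact, equal opportunity difference,
    average odds difference, predictive parity difference), and five
    debiasing approaches combining fairness through blindness and
    Kamiran-Calders reweighing. An orchestration layer evaluates every
    approach across datasets and decision thresholds and assembles a
    performance-and-fairness grid with improvement flags.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
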