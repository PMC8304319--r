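Package: pedosa
Title: Screening Models for Severe Pediatric Obstructive Sleep Apnea from
    Home Sleep Apnea Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to screen for severe pediatric obstructive sleep apnea
    (OSA) from home sleep apnea tests and anatomical findings. Computes the
    3% oxygen desaturation index (ODI3) from nocturnal pulse-oximetry traces
    cleaned of motion artifacts and restricted to a 90-minute window after
    the first snore; detects snores in overnight audio against a background
    noise baseline and derives the snore index and band-limited snoring
    sound energy (SSE) by short-window spectral analysis; dichotomizes
    predictors at Youden-optimal cut-offs; fits univariate logistic models
    and a bootstrapped logistic LASSO for variable selection; scores
    patients with anatomical, home-sleep-apnea-test, and weighted combined
    screening models; and evaluates them with diagnostic-accuracy and
    agreement statistics (sensitivity, specificity, predictive values,
    odds ratios, AUC, Cohen's kappa, Hodges-Lehmann effect sizes). A seeded
    synthetic-data module generates cohorts, oximetry traces, and snore
    audio with severity-dependent structure so the full pipeline is testable
    without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    dplyr,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
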