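Package: amprog
Title: Recovery Prediction Scoring for Acute Mediastinitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Three-factor prognostic scoring for patients admitted with
    acute mediastinitis. Computes proteinic-status, inflammatory-status
    and general-risk factor scores from eight admission parameters via
    published standardization constants and factor-score weights, applies
    per-factor recovery thresholds with configurable vote combination,
    and evaluates diagnostic power (sensitivity/specificity). Also
    provides the exploratory factor-analysis machinery used to derive
    such scales (principal-component extraction on the correlation
    matrix, Kaiser retention, varimax rotation, communalities, factor
    scoring), two-group validation statistics (one-way ANOVA, Levene,
    Kruskal-Wallis, descriptive summaries), a seeded latent-factor
    synthetic cohort generator for parameter-recovery experiments, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    car,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
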