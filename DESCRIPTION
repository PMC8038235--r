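Package: actasym
Title: Dual-Wrist Actigraphic Asymmetry Index and Stroke Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the 24-hour upper-limb Asymmetry Rate Index (AR2_24h)
    from raw dual-wrist tri-axial accelerometer recordings of acute stroke
    patients, via the first eigenvector of the paired per-epoch activity
    cloud, and evaluates its prognostic accuracy for 90-day disability
    (modified Rankin Scale): Spearman correlation, empirical ROC with
    Youden-optimal cut-off, sensitivity/specificity/predictive values and
    likelihood ratios, Fagan post-test probabilities, and Hanley-McNeil
    ROC sample-size calculation. Includes a synthetic dual-wrist cohort
    generator with known ground-truth asymmetry for end-to-end validation,
    a packaged 20-patient cohort table, ggplot2 figures, and broom-style
    tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
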