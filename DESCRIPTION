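Package: ichtriage
Title: Rule-Based Triage of Intracerebral Hemorrhage from Emergency Medical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for turning narrative emergency medical
    records of intracerebral hemorrhage (ICH) patients into treatment-plan
    recommendations. Narrative sections (chief complaint, history, physical
    examination, CT report) are normalized and scanned with a dictionary and
    regular-expression entity recognizer; extracted clinical variables (GCS,
    vital signs, pupil state, hematoma location and volume, midline shift,
    ventricular involvement) feed a configurable weighted logic table that
    scores each case and classifies it as emergency surgery (Plan I),
    non-surgical unstable (Plan IIA), or non-surgical stable (Plan IIB).
    Includes a seeded synthetic eEMR generator with a controllable noise model
    (misspellings, symbol noise, abbreviations, field dropout, unit variants)
    for end-to-end testing, and an evaluation suite with sensitivity,
    specificity, accuracy, PPV, NPV and their confidence intervals, ROC/AUC,
    per-plan accuracy, and Cohen's kappa.
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
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
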