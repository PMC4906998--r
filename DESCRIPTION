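Package: airwaysyn
Title: Bliss Independence Synergy Analysis for Airway Organ-Bath Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies pharmacological interaction between bronchodilators in
    human isolated airway preparations. Fits variable-slope sigmoid
    concentration-response curves (four-parameter logistic) to organ-bath and
    precision-cut lung slice data normalized to the papaverine maximal
    relaxation, derives pEC50, EC_n and isoeffective concentration designs,
    computes Bliss Independence expected effects for two- and three-drug
    combinations with replicate (subject-level) uncertainty, classifies
    interactions as synergistic, additive or antagonistic, and analyzes 12-hour
    electrical-field-stimulation time courses (onset t1/2, maximal relaxation,
    plateau, interval AUC of the observed-minus-expected synergism curve, and
    duration of synergism). Includes a seeded synthetic-data generator that
    emulates the organ-bath study designs with configurable injected synergy,
    so the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    pracma,
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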