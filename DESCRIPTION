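Package: rbcscore
Title: Derivation and Validation of Pre-Operative Transfusion Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving integer point systems that predict the
    probability of perioperative red-blood-cell transfusion from
    pre-operative patient characteristics. Implements exhaustive
    best-subset logistic model selection over repeated stratified
    train/test resamples with mean test-set AUC as the selection
    criterion, nested resampling for optimism-corrected internal
    validation, and conversion of a fitted logistic model into a
    Sullivan-style integer risk score with a score-to-probability
    look-up table. Includes a synthetic cohort generator emulating a
    spine-surgery transfusion cohort for testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
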