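Package: symptomweak
Title: Weakly Supervised Symptom Extraction from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building note-level symptom classifiers from
    electronic health record text without manual annotation. Training
    labels for the ten ICD-10 symptom categories R00-R09 are derived
    either from encounter diagnosis codes (high specificity, low
    sensitivity) or from a weak-supervision pipeline (dictionary mention
    detection, 20-token context windows, negation/history/family trigger
    labeling functions, an optional EM label model, and note-level
    aggregation). Includes four document featurizations (bag-of-words,
    TF-IDF, embedding averages, PV-DBOW paragraph vectors), one-vs-all
    logistic regression and random forest classifiers, the full metric
    battery (recall, F1, average precision, AUROC, ROC/PR curves),
    mention-to-note majority voting for external validation, and a
    seeded synthetic clinical-note generator with known ground truth for
    end-to-end evaluation under controlled label noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    randomForest,
    withr,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
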