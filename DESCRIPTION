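Package: longnote
Title: Clinical Event Prediction from Long Free-Text Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts clinical events (hospital re-admission, fatality) from
    long free-text documents such as discharge summaries.  Implements a suite
    of text classifiers spanning bag-of-words logistic regression, mean-pooled
    n-gram embeddings, convolutional and recurrent baselines, and a simplified
    single-head attention encoder, together with seven segment-combination
    architectures (recurrent, concatenation and pooling heads over per-segment
    CLS vectors) that extend the fixed-window encoder to documents far longer
    than its input limit.  Includes boolean attribute fusion, a grouped
    train/validation/test evaluation protocol with minority oversampling and
    ROC-AUC model comparison, and a synthetic discharge-summary generator with
    planted, position-controllable class signal so that every mechanism is
    testable without access to restricted clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
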