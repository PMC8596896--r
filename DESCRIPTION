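Package: swam
Title: Shallow and Wide Attention Convolutional Networks for Explainable
    Multi-Label Clinical Code Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns sets of medical codes (such as ICD-9 diagnosis and
    procedure codes) to free-text clinical documents with a shallow, wide
    convolutional network whose per-label attention layer both pools the
    convolutional features and extracts the text snippet that drove each
    prediction.  Includes the full pipeline: corpus readers and writers,
    clinical-text preprocessing (alphabetic token filter, document-frequency
    vocabulary, truncation, top-k label selection, patient-level splits),
    CBOW embedding pretraining, mini-batch training with early stopping on
    validation macro-F1, grid search, the standard multi-label metric suite
    (macro/micro F1 and AUC, precision-at-n, paired bootstrap), a unigram
    bag-of-words logistic-regression baseline, attention-based snippet
    explanations, and a planted-snippet synthetic corpus generator that makes
    the network-width ablation and data-shuffle experiments reproducible on a
    laptop.
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
    glmnet,
    jsonlite,
    Matrix,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
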