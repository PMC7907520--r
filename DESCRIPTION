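Package: radiomap
Title: Radiomics Feature Mapping and Squeeze-and-Excitation CNN
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting binary genotypes (such as EGFR mutation
    status in lung adenocarcinoma) from tabular CT radiomics features.
    Features are ranked by random-forest mean-decrease-impurity importance,
    the top square number of features is arranged into a 2D "feature
    mapping" by a center-out counterclockwise spiral, and the mapping is
    classified with a compact squeeze-and-excitation convolutional neural
    network trained with Adam and early stopping. Includes ablations (CNN
    without SE, 1D-CNN), classical machine-learning baselines (SVM, random
    forest, MLP on radiomics, clinical and combined features), a synthetic
    cohort generator with controllable class separation, and ROC/AUC-based
    evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ranger,
    randomForest,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
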