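Package: attmil
Title: Attention-Based Multiple Instance Learning for Multi-Magnification Slide Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised classification of whole-slide images via
    attention-based multiple instance learning. Slides are tiled into
    non-overlapping 224x224 patches at three magnifications (20x, 10x, 5x),
    background tiles are removed by a Shannon-entropy filter, and each
    magnification trains its own attention-pooled bag classifier whose
    per-slide probabilities are mean-pooled into a single ensemble risk.
    Includes a synthetic-data generator for multi-scale slide images and
    feature-space bags with known ground truth, 5-fold cross-validation with
    best-model selection, and evaluation (AUC, accuracy, FPR, FNR) with
    stratified bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
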