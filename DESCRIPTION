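Package: hiwcf
Title: Hybrid Interpolation Weighted Collaborative Filtering for
    Anti-Cancer Drug Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts missing drug sensitivity values in partially observed
    cell-line by drug response matrices (log-IC50 or activity area) with a
    neighbourhood collaborative filtering model. A baseline of global mean
    plus regularised per-cell-line and per-drug biases is combined with a
    dual cell-line-/drug-oriented k-nearest-neighbour interpolation whose
    weights come from gene-expression correlation (COEF), chemical
    fingerprint Jaccard similarity, response-profile correlation (RPCC) or
    their product (MRPCC), after support-based shrinkage and case
    amplification. Includes a cross-validation evaluation harness with
    per-drug Pearson correlation and RMSE (overall and on each drug's
    sensitive/resistant cell lines) and a synthetic-data generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'baseline.R'
    'similarity.R'
    'prediction.R'
    'evaluation.R'
    'synthetic.R'
    'hiwcf-package.R'
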