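Package: pairf
Title: Personalized Advantage Index Analysis with Random-Forest Counterfactual Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individualized treatment-allocation analysis for two-arm
    observational cohorts via the Personalized Advantage Index (PAI):
    random-forest outcome models tuned by nested cross-validation with
    embedded near-zero-variance filtering and permutation-importance
    feature selection, counterfactual prediction by treatment-label
    flipping, PAI threshold-sweep inference with Benjamini-Hochberg
    correction, permutation-based model evaluation, propensity-score
    matching with balance diagnostics, and exact path-dependent tree-SHAP
    attributions and interaction values for prognostic and prescriptive
    interpretation. Includes a synthetic-cohort simulator with known
    ground-truth individualized treatment effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ranger,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
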