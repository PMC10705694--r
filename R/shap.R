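#' Extract forest structure for SHAP computation
#'
#' Converts a fitted `pai_rfr` into flat per-tree arrays (children, split
#' feature, threshold, leaf values) and computes each node's cover — the
#' bootstrap (in-bag) training weight reaching it — which path-dependent
#' SHAP uses to weight the branches a "missing" feature could have taken.
#' The result is cached on the model.
#'
#' @param model a `pai_rfr` from [fit_rfr()].
#' @return list of tree structures (class `shap_forest`) with attribute
#'   `features`.
#' @export
shap_forest <- function(model) {
  stopifnot(inherits(model, "pai_rfr"))
  if (!is.null(model$cache$forest)) return(model$cache$forest)
  rf <- model$rf
  Xm <- as.matrix(model$X_train[, model$features, drop = FALSE])
  storage.mode(Xm) <- "double"
  trees <- lapply(seq_len(rf$num.trees), function(t) {
    ti <- ranger::treeInfo(rf, t)
    leaf <- ti$terminal
    left <- ifelse(leaf, -1L, ti$leftChild)
    right <- ifelse(leaf, -1L, ti$rightChild)
    feature <- ifelse(leaf, -1L, ti$splitvarID)
    threshold <- ifelse(leaf, 0, ti$splitval)
    value <- ifelse(leaf, ti$prediction, 0)
    w <- as.numeric(rf$inbag.counts[[t]])
    cover <- cpp_node_cover(as.integer(left), as.integer(right),
                            as.integer(feature), as.numeric(threshold), Xm, w)
    if (any(cover <= 0)) stop("tree ", t, " contains a node with zero bootstrap cover")
    list(left = as.integer(left), right = as.integer(right),
         feature = as.integer(feature), threshold = as.numeric(threshold),
         value = as.numeric(value), cover = as.numeric(cover))
  })
  out <- structure(trees, class = "shap_forest", features = model$features)
  if (!is.null(model$cache)) model$cache$forest <- out
  out
}

as_shap_matrix <- function(X, features) {
  Xm <- as.matrix(as.data.frame(X)[, features, drop = FALSE])
  storage.mode(Xm) <- "double"
  Xm
}

#' SHAP values for a fitted forest
#'
#' Path-dependent tree-SHAP attributions: for each patient, a per-feature
#' additive decomposition (in QIDS points) of the model prediction around
#' the baseline (the cover-weighted expected prediction, i.e. the sample
#' average anchor). Satisfies local accuracy: `baseline + rowSums(phi)`
#' equals the model prediction.
#'
#' @param model a `pai_rfr`.
#' @param X data to explain (defaults to the training data).
#' @param patient_id optional row identifiers.
#' @return a `pai_explanation` list: `phi` (n x p matrix), `baseline`,
#'   `pred` (model predictions), `X` (feature values explained),
#'   `patient_id`.
#' @export
shap_values <- function(model, X = model$X_train, patient_id = NULL) {
  forest <- shap_forest(model)
  feats <- attr(forest, "features")
  Xm <- as_shap_matrix(X, feats)
  phi <- cpp_forest_shap(forest, Xm, length(feats))
  colnames(phi) <- feats
  structure(list(
    phi = phi,
    baseline = cpp_forest_expected(forest),
    pred = cpp_forest_predict(forest, Xm),
    X = as.data.frame(X)[, feats, drop = FALSE],
    patient_id = patient_id %||% rownames(Xm) %||% sprintf("P%05d", seq_len(nrow(Xm))),
    interaction = NULL
  ), class = "pai_explanation")
}

#' SHAP interaction values
#'
#' Pairwise decomposition of the attributions: for each patient a symmetric
#' p x p matrix whose off-diagonal entries are the Shapley interaction
#' values (computed from conditional tree-SHAP runs with each feature fixed
#' present/absent) and whose diagonal holds the main effects, so every row
#' sums to that feature's SHAP value.
#'
#' @param model a `pai_rfr`.
#' @param X data to explain (defaults to the training data).
#' @param patient_id optional row identifiers.
#' @return a `pai_explanation` with the `interaction` field set
#'   (n x p x p array).
#' @export
shap_interactions <- function(model, X = model$X_train, patient_id = NULL) {
  expl <- shap_values(model, X, patient_id)
  forest <- shap_forest(model)
  feats <- attr(forest, "features")
  Xm <- as_shap_matrix(X, feats)
  expl$interaction <- forest_shap_interactions(forest, Xm, expl$phi)
  expl
}

# interaction assembly from conditional runs: phi with feature i present
# minus phi with it absent, halved; main effects close the row sums
forest_shap_interactions <- function(forest, Xm, phi) {
  feats <- attr(forest, "features")
  p <- length(feats)
  n <- nrow(Xm)
  inter <- array(0, dim = c(n, p, p), dimnames = list(NULL, feats, feats))
  for (i in seq_len(p)) {
    on <- cpp_forest_shap(forest, Xm, p, condition = 1L, condition_feature = i - 1L)
    off <- cpp_forest_shap(forest, Xm, p, condition = -1L, condition_feature = i - 1L)
    inter[, i, ] <- (on - off) / 2
    inter[, i, i] <- 0
  }
  for (i in seq_len(p)) {
    inter[, i, i] <- phi[, i] - rowSums(inter[, i, , drop = FALSE], dims = 2)
  }
  inter
}

#' @export
print.pai_explanation <- function(x, ...) {
  cat("SHAP explanation:", nrow(x$phi), "patients x", ncol(x$phi),
      "features; baseline =", round(x$baseline, 3),
      if (!is.null(x$interaction)) "(with interactions)" else "", "\n")
  invisible(x)
}

#' Global SHAP importance ranking
#'
#' Features ranked by mean absolute SHAP value across patients — the
#' prognostic-importance summary behind the usual beeswarm/bar displays.
#'
#' @param explanation a `pai_explanation`.
#' @param top_k rows to return (default all).
#' @return data.frame `feature`, `importance` (mean |phi|, QIDS points),
#'   sorted descending (ties by column order).
#' @export
global_importance <- function(explanation, top_k = ncol(explanation$phi)) {
  imp <- colMeans(abs(explanation$phi))
  ord <- order(-imp, seq_along(imp))
  head(data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
                  stringsAsFactors = FALSE), top_k)
}

#' Treatment-interaction (prescriptive) profile of a feature
#'
#' Extracts, per patient, the SHAP interaction value between a predictor
#' and the treatment indicator together with the predictor's observed value
#' and the received arm — the raw material of a prescriptive interaction
#' plot. Values above zero push the prediction toward higher min-QIDS
#' (worse outcome) for that patient's arm configuration. A sign summary
#' reports, for patients below and above the feature's median, which arm
#' the model expects to do better (lower predicted min-QIDS).
#'
#' @param explanation a `pai_explanation` with interactions.
#' @param feature predictor name (not the treatment column itself).
#' @param treatment_col treatment indicator name.
#' @return data.frame `patient_id`, `value`, `interaction`, `arm`, with a
#'   `sign_summary` attribute.
#' @export
prescriptive_profile <- function(explanation, feature,
                                 treatment_col = "treatment") {
  if (is.null(explanation$interaction)) stop("explanation has no interaction values; use shap_interactions()")
  feats <- colnames(explanation$phi)
  if (!feature %in% feats) stop("feature not in the model: ", feature)
  if (identical(feature, treatment_col)) stop("the treatment feature has no interaction profile with itself")
  if (!treatment_col %in% feats) stop("treatment feature not retained by the model")

  val <- explanation$X[[feature]]
  arm01 <- explanation$X[[treatment_col]]
  inter <- explanation$interaction[, feature, treatment_col]
  out <- data.frame(patient_id = explanation$patient_id, value = val,
                    interaction = inter,
                    arm = ifelse(arm01 == 1, "ECT", "KET"),
                    stringsAsFactors = FALSE)

  med <- stats::median(val)
  hi <- val > med
  # binary/saturated features: fall back so both sides are populated
  if (!any(hi) || all(hi)) hi <- val >= med
  if (!any(hi) || all(hi)) hi <- val > min(val)
  lohi <- ifelse(hi, "high", "low")
  favored <- function(side) {
    # total treatment-attributable push (phi for treatment feature is the
    # cleaner per-patient summary: negative = received arm beneficial)
    m_ect <- mean(explanation$phi[lohi == side & arm01 == 1, treatment_col])
    m_ket <- mean(explanation$phi[lohi == side & arm01 == 0, treatment_col])
    if (is.nan(m_ect) || is.nan(m_ket)) return(NA_character_)
    if (m_ect < m_ket) "ECT" else "KET"
  }
  attr(out, "sign_summary") <- data.frame(
    side = c("low", "high"), cutoff = med,
    favored_arm = c(favored("low"), favored("high")),
    mean_interaction = c(mean(inter[lohi == "low"]), mean(inter[lohi == "high"])),
    stringsAsFactors = FALSE
  )
  out
}

#' Per-patient SHAP waterfall table
#'
#' Contributions sorted by absolute size with the remainder aggregated as
#' `"other"`; the cumulative column runs from the baseline (sample-average
#' prediction) to the patient's prediction exactly.
#'
#' @param explanation a `pai_explanation`.
#' @param patient_id patient to decompose.
#' @param top_k individually listed features; the rest are pooled.
#' @return data.frame `feature`, `value`, `phi`, `cumulative`, with
#'   attributes `baseline` and `prediction`.
#' @export
waterfall <- function(explanation, patient_id, top_k = 10L) {
  i <- match(patient_id, explanation$patient_id)
  if (is.na(i)) stop("unknown patient_id: ", patient_id)
  phi <- explanation$phi[i, ]
  ord <- order(-abs(phi), seq_along(phi))
  top_k <- min(top_k, length(phi))
  keep <- ord[seq_len(top_k)]
  rest <- setdiff(ord, keep)
  out <- data.frame(
    feature = c(colnames(explanation$phi)[keep], if (length(rest)) "other"),
    value = c(as.numeric(explanation$X[i, keep]), if (length(rest)) NA_real_),
    phi = c(unname(phi[keep]), if (length(rest)) sum(phi[rest])),
    stringsAsFactors = FALSE
  )
  out$cumulative <- explanation$baseline + cumsum(out$phi)
  attr(out, "baseline") <- explanation$baseline
  attr(out, "prediction") <- explanation$pred[i]
  out
}
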