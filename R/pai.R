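#' PAI scores from factual and counterfactual predictions
#'
#' The Personalized Advantage Index is the absolute difference between a
#' patient's predicted outcome under the received treatment and under the
#' counterfactual (label-flipped) treatment. The arm with the smaller
#' predicted min-QIDS is the predicted-optimal treatment; ties count as
#' having received the optimal treatment (a patient with no predicted
#' advantage is not disadvantaged either way).
#'
#' @param pred_actual predicted outcome under the received arm.
#' @param pred_flipped predicted outcome under the other arm.
#' @param received_arm character/factor of received arms (`"ECT"`/`"KET"`).
#' @param patient_id optional identifiers.
#' @return data.frame: `patient_id`, `received`, `pred_actual`,
#'   `pred_flipped`, `predicted_optimal`, `pai`, `received_optimal`.
#' @export
compute_pai <- function(pred_actual, pred_flipped, received_arm,
                        patient_id = NULL) {
  stopifnot(length(pred_actual) == length(pred_flipped),
            length(pred_actual) == length(received_arm))
  if (!all(is.finite(pred_actual)) || !all(is.finite(pred_flipped))) {
    stop("non-finite predictions")
  }
  received <- as.character(received_arm)
  stopifnot(all(received %in% ARM_LEVELS))
  other <- ifelse(received == "ECT", "KET", "ECT")
  received_optimal <- pred_actual <= pred_flipped
  data.frame(
    patient_id = patient_id %||% sprintf("P%05d", seq_along(pred_actual)),
    received = received,
    pred_actual = pred_actual,
    pred_flipped = pred_flipped,
    predicted_optimal = ifelse(received_optimal, received, other),
    pai = abs(pred_actual - pred_flipped),
    received_optimal = received_optimal,
    stringsAsFactors = FALSE
  )
}

# flip the treatment column of a model-ready feature table (ECT <-> KET)
flip_treatment <- function(X, treatment_col = "treatment") {
  X[[treatment_col]] <- 1 - X[[treatment_col]]
  X
}

# cohort -> model-ready numeric feature table (treatment as 0/1, ECT = 1)
build_feature_table <- function(cohort, treatment_col = "treatment") {
  X <- cohort[, predictor_columns(cohort), drop = FALSE]
  X[[treatment_col]] <- as.numeric(as.character(cohort$treatment) == "ECT")
  nonnum <- names(X)[!vapply(X, is.numeric, TRUE)]
  for (v in nonnum) X[[v]] <- as.numeric(as.factor(X[[v]])) - 1
  X
}

#' Counterfactual prediction over outer cross-validation
#'
#' For each outer partition, runs the full embedded model-building procedure
#' ([nested_cv_train()]) on the training side, then predicts each held-out
#' patient twice: once with the recorded treatment label and once with the
#' label switched. Leave-one-out (`outer = "loo"`) is the study-scale
#' scheme; k-fold (`outer = "kfold"`) is the desk-scale surrogate and is
#' recorded in the output metadata.
#'
#' @param cohort imputed cohort (no missing predictor values).
#' @param grid a [tuning_grid()] for the embedded tuning.
#' @param outer `"kfold"` or `"loo"`.
#' @param k outer folds when `outer = "kfold"`.
#' @param n_trees trees per forest.
#' @param importance_repeats permutations per feature in the embedded
#'   ranking step.
#' @param seed integer seed.
#' @return data.frame of per-patient counterfactual results (see
#'   [compute_pai()]), with attributes `outer` (scheme label) and `models`
#'   (per-fold winning parameters).
#' @export
counterfactual_predict <- function(cohort, grid = tuning_grid(),
                                   outer = c("kfold", "loo"), k = 10L,
                                   n_trees = 1000L, importance_repeats = 3L,
                                   seed = 1L) {
  outer <- match.arg(outer)
  X <- build_feature_table(cohort)
  y <- cohort$min_qids
  if (anyNA(X)) stop("cohort must be imputed before counterfactual prediction")
  n <- nrow(X)
  folds <- if (outer == "loo") seq_len(n) else make_folds(n, k, spawn_seed(seed, "outer_folds"))
  nfold <- length(unique(folds))

  pred_actual <- pred_flipped <- rep(NA_real_, n)
  models <- vector("list", nfold)
  for (f in sort(unique(folds))) {
    te <- folds == f
    if (length(unique(X$treatment[!te])) < 2L) {
      stop("outer training partition ", f, " contains a single treatment level")
    }
    tm <- nested_cv_train(X[!te, , drop = FALSE], y[!te], grid = grid,
                          seed = spawn_seed(seed, "outer_train", f),
                          n_trees = n_trees,
                          importance_repeats = importance_repeats)
    models[[f]] <- tm$params
    Xte <- X[te, , drop = FALSE]
    pred_actual[te] <- predict(tm$model, Xte)
    pred_flipped[te] <- predict(tm$model, flip_treatment(Xte))
  }
  out <- compute_pai(pred_actual, pred_flipped, cohort$treatment,
                     patient_id = cohort$patient_id)
  attr(out, "outer") <- if (outer == "loo") "loo" else sprintf("kfold:%d", k)
  attr(out, "models") <- models
  out
}

#' One-sided Welch two-sample t-test
#'
#' Tests the a-priori directional hypothesis that group `a` (patients who
#' received their predicted-optimal treatment) has the lower mean outcome
#' than group `b`: alternative mean(a) < mean(b). Welch statistic with
#' Satterthwaite degrees of freedom. With zero variance in both groups and
#' equal means the test is uninformative and returns p = 0.5 by convention.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list with `t`, `df`, `p` (one-sided).
#' @export
one_sided_t <- function(a, b) {
  wt <- welch_t(a, b)
  list(t = wt$t, df = wt$df, p = wt$p_less)
}

#' Cohen's d (pooled SD)
#'
#' Absolute standardized mean difference with the classical pooled standard
#' deviation (n - 1 weights).
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return `d`, or `NA` when the pooled SD is zero (undefined).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) return(NA_real_)
  abs(mean(b) - mean(a)) / sqrt(sp2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1.
#'
#' @param pvals p-values in \[0, 1\] (NAs passed through).
#' @return adjusted q-values.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

#' PAI threshold sweep
#'
#' For each threshold on the grid \{0, 0.1, ...\} up to the maximum PAI
#' score, restricts to patients with `pai >= threshold`, splits them by
#' whether they received their predicted-optimal treatment, and compares
#' observed outcomes: group sizes, means, mean difference (non-optimal
#' minus optimal; positive supports the allocation hypothesis), one-sided
#' Welch t, BH-adjusted q across all testable rows, and Cohen's d.
#' Thresholds where either group has fewer than 2 patients carry undefined
#' statistics and are excluded from the adjustment.
#'
#' @param results counterfactual results ([counterfactual_predict()]).
#' @param outcomes observed outcomes aligned with `results` (defaults to
#'   matching by nothing — supply the cohort's `min_qids`).
#' @param step threshold step in PAI units (study value 0.1).
#' @return data.frame of sweep rows: `threshold`, `n_optimal`,
#'   `n_nonoptimal`, `mean_optimal`, `mean_nonoptimal`, `mean_difference`,
#'   `t`, `p`, `q`, `cohens_d`, `testable`.
#' @export
threshold_sweep <- function(results, outcomes, step = 0.1) {
  stopifnot(nrow(results) >= 1L, length(outcomes) == nrow(results), step > 0)
  grid <- seq(0, max(results$pai), by = step)
  rows <- lapply(grid, function(th) {
    inset <- results$pai >= th
    opt <- outcomes[inset & results$received_optimal]
    non <- outcomes[inset & !results$received_optimal]
    row <- data.frame(
      threshold = th, n_optimal = length(opt), n_nonoptimal = length(non),
      mean_optimal = if (length(opt)) mean(opt) else NA_real_,
      mean_nonoptimal = if (length(non)) mean(non) else NA_real_,
      mean_difference = NA_real_, t = NA_real_, p = NA_real_,
      cohens_d = NA_real_, testable = length(opt) >= 2L && length(non) >= 2L
    )
    if (!is.na(row$mean_optimal) && !is.na(row$mean_nonoptimal)) {
      row$mean_difference <- row$mean_nonoptimal - row$mean_optimal
    }
    if (row$testable) {
      tt <- one_sided_t(opt, non)
      row$t <- tt$t; row$p <- tt$p
      row$cohens_d <- cohens_d(opt, non)
    }
    row
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(ifelse(out$testable, out$p, NA))
  out[, c("threshold", "n_optimal", "n_nonoptimal", "mean_optimal",
          "mean_nonoptimal", "mean_difference", "t", "p", "q", "cohens_d",
          "testable")]
}
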