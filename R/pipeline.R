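#' Matching covariate presets
#'
#' Named covariate sets for propensity matching: `full` (baseline QIDS, age,
#' inpatient status, BASIS psychosis — the primary analysis), and the
#' sensitivity sets `qids_only`, `qids_age`, `qids_age_inpatient`.
#'
#' @return named list of covariate-name vectors.
#' @export
matching_presets <- function() {
  list(
    full = c("qids_baseline", "age", "inpatient", "basis_psychosis"),
    qids_only = "qids_baseline",
    qids_age = c("qids_baseline", "age"),
    qids_age_inpatient = c("qids_baseline", "age", "inpatient")
  )
}

#' Pipeline run configuration
#'
#' @param cohort a `pai_sim` (from [simulate_cohort()]), a cohort
#'   data.frame, or a CSV path readable by [read_cohort()].
#' @param matching preset name (see [matching_presets()]) or a character
#'   vector of covariates; `NULL` skips matching (pre-matched data).
#' @param grid learner [tuning_grid()].
#' @param outer `"kfold"` or `"loo"`; `k` outer folds for the former.
#' @param k outer folds.
#' @param n_trees trees per forest.
#' @param importance_repeats permutations per feature in the embedded
#'   feature-ranking step.
#' @param sweep_step PAI threshold step.
#' @param B permutations for the model-evaluation test; `0` skips it.
#' @param explain compute SHAP (and interaction) tables for the global
#'   model.
#' @param explain_n number of patients (sampled by seed) the interaction
#'   explanation is computed for; `Inf` for the whole analysis cohort.
#'   Interaction values cost two conditional SHAP passes per feature, so
#'   subsampling keeps large runs tractable without touching the model.
#' @param caliper matching caliper in logit SDs, or `NULL`.
#' @param seed integer seed (mandatory; every stage derives from it).
#' @param out_dir output directory for artifacts, or `NULL` for none.
#' @param verbose log one line per stage.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort = sim_config(), matching = "full",
                       grid = minimal_grid(), outer = "kfold", k = 10L,
                       n_trees = 500L, importance_repeats = 3L,
                       sweep_step = 0.1, B = 0L,
                       explain = TRUE, explain_n = Inf, caliper = NULL,
                       seed = 1L, out_dir = NULL, verbose = FALSE) {
  if (is.character(matching) && length(matching) == 1L &&
      matching %in% names(matching_presets())) {
    matching <- matching_presets()[[matching]]
  }
  structure(list(cohort = cohort, matching = matching, grid = grid,
                 outer = outer, k = as.integer(k),
                 n_trees = as.integer(n_trees),
                 importance_repeats = as.integer(importance_repeats),
                 sweep_step = sweep_step,
                 B = as.integer(B), explain = explain, explain_n = explain_n,
                 caliper = caliper,
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = verbose),
            class = "run_config")
}

resolve_cohort <- function(config) {
  src <- config$cohort
  if (inherits(src, "sim_config")) {
    sim <- simulate_cohort(src)
    list(cohort = sim$cohort, truth = sim$truth)
  } else if (inherits(src, "pai_sim")) {
    list(cohort = src$cohort, truth = src$truth)
  } else if (is.character(src)) {
    list(cohort = read_cohort(src), truth = NULL)
  } else if (is.data.frame(src)) {
    check_cohort_schema(src)
    list(cohort = src, truth = NULL)
  } else {
    stop("unsupported cohort source")
  }
}

#' Run the full PAI pipeline
#'
#' Stage order: simulate/load, inclusion filter (pretreatment QIDS >= 10),
#' propensity matching, within-arm imputation, counterfactual prediction
#' over the outer CV, PAI threshold sweep, global-model evaluation
#' (R-squared, optionally its permutation test), and SHAP explanation.
#' Rows with missing matching covariates are excluded before matching with
#' a logged count (the mode/mean imputation serves the modeling covariates
#' and runs on the matched cohort).
#'
#' @param config a [run_config()].
#' @return a `run_report` list: `cohort` (analysis cohort), `match`,
#'   `counterfactual`, `sweep`, `eval`, `explanation`, `importance`,
#'   `summary` (plain-list summary, also written to `summary.json` when
#'   `out_dir` is set), `truth` when simulated.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  src <- resolve_cohort(config)
  cohort <- src$cohort
  log_stage(config$verbose, "load", nrow(cohort), "patients")

  n_excl_inclusion <- sum(cohort$qids_baseline < 10, na.rm = TRUE)
  cohort <- cohort[is.na(cohort$qids_baseline) | cohort$qids_baseline >= 10, , drop = FALSE]

  match_res <- NULL
  if (!is.null(config$matching)) {
    covs <- config$matching
    ok <- complete.cases(cohort[, covs, drop = FALSE])
    if (any(!ok)) {
      log_stage(config$verbose, "match",
                sum(!ok), "rows excluded: missing matching covariates")
    }
    matchable <- cohort[ok, , drop = FALSE]
    ps <- estimate_propensity(matchable, covs)
    match_res <- match_1to1(matchable, ps$propensity, caliper = config$caliper,
                            covariates = covs, seed = spawn_seed(config$seed, "matching"))
    cohort <- matchable[matchable$patient_id %in% match_res$matched_ids, , drop = FALSE]
    log_stage(config$verbose, "match", nrow(match_res$pairs), "pairs")
  }
  rownames(cohort) <- NULL

  cohort <- impute(cohort)
  log_stage(config$verbose, "impute", "done")

  arm_comparison <- compare_arms(cohort)

  cf <- counterfactual_predict(cohort, grid = config$grid,
                               outer = config$outer, k = config$k,
                               n_trees = config$n_trees,
                               importance_repeats = config$importance_repeats,
                               seed = config$seed)
  log_stage(config$verbose, "counterfactual", nrow(cf), "patients")

  sweep <- threshold_sweep(cf, cohort$min_qids, step = config$sweep_step)
  log_stage(config$verbose, "sweep", nrow(sweep), "thresholds")

  # global model: same embedded procedure without the outer loop
  global <- nested_cv_train(build_feature_table(cohort), cohort$min_qids,
                            grid = config$grid,
                            seed = spawn_seed(config$seed, "global"),
                            n_trees = config$n_trees,
                            importance_repeats = config$importance_repeats)
  r2_cv <- r_squared(cohort$min_qids, cf$pred_actual)
  eval_res <- list(r2_cv = r2_cv, permutation = NULL)
  if (config$B > 0L) {
    runner <- make_cv_r2_runner(config)
    eval_res$permutation <- permutation_test(runner, cohort, B = config$B,
                                             seed = spawn_seed(config$seed, "permtest"))
  }
  log_stage(config$verbose, "evaluate", sprintf("r2_cv=%.3f", r2_cv))

  explanation <- NULL
  importance <- NULL
  if (isTRUE(config$explain)) {
    idx <- seq_len(nrow(cohort))
    if (is.finite(config$explain_n) && config$explain_n < nrow(cohort)) {
      set.seed(spawn_seed(config$seed, "explain_sample"))
      idx <- sort(sample(idx, config$explain_n))
    }
    explanation <- shap_interactions(global$model,
                                     X = global$model$X_train[idx, , drop = FALSE],
                                     patient_id = cohort$patient_id[idx])
    importance <- global_importance(explanation, top_k = 10L)
    log_stage(config$verbose, "explain", length(idx), "patients")
  }

  summary <- list(
    n_patients = nrow(cohort),
    n_excluded_inclusion = n_excl_inclusion,
    matched_per_arm = if (is.null(match_res)) NA else nrow(match_res$pairs),
    outer = attr(cf, "outer"),
    fraction_received_optimal = mean(cf$received_optimal),
    predicted_optimal_by_arm = as.list(table(cf$predicted_optimal)),
    r2_cv = r2_cv,
    permutation_p = if (!is.null(eval_res$permutation)) eval_res$permutation$permutation_p else NA,
    sweep = sweep,
    top_importance = importance,
    seed = config$seed,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  report <- structure(list(cohort = cohort, truth = src$truth,
                           match = match_res, arm_comparison = arm_comparison,
                           counterfactual = cf,
                           sweep = sweep, global_model = global,
                           eval = eval_res, explanation = explanation,
                           importance = importance, summary = summary,
                           config = config),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Outcome-permutable model-fit runner used by the permutation test: same
# embedded training procedure, scored by outer-CV R^2.
make_cv_r2_runner <- function(config) {
  function(cohort, seed) {
    cf <- counterfactual_predict(cohort, grid = config$grid,
                                 outer = config$outer, k = config$k,
                                 n_trees = config$n_trees,
                                 importance_repeats = config$importance_repeats,
                                 seed = seed)
    r_squared(cohort$min_qids, cf$pred_actual)
  }
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(report$cohort, file.path(out_dir, "cohort.csv"))
  if (!is.null(report$truth)) {
    jsonlite::write_json(report$truth, file.path(out_dir, "truth.json"),
                         dataframe = "rows", digits = NA)
  }
  if (!is.null(report$match)) {
    jsonlite::write_json(
      list(pairs = report$match$pairs,
           excluded_ids = report$match$excluded_ids,
           smd_before = as.list(report$match$smd_before),
           smd_after = as.list(report$match$smd_after)),
      file.path(out_dir, "match.json"), auto_unbox = TRUE, digits = NA)
  }
  write.csv(report$arm_comparison, file.path(out_dir, "arm_comparison.csv"),
            row.names = FALSE)
  write.csv(report$counterfactual, file.path(out_dir, "counterfactual.csv"),
            row.names = FALSE)
  write.csv(report$sweep, file.path(out_dir, "sweep.csv"), row.names = FALSE)
  if (!is.null(report$importance)) {
    write.csv(report$importance, file.path(out_dir, "shap_importance.csv"),
              row.names = FALSE)
  }
  s <- report$summary
  s$sweep <- NULL; s$top_importance <- NULL; s$elapsed_sec <- NULL
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat("PAI pipeline run (", s$outer, ", seed ", s$seed, ")\n", sep = "")
  cat("  analysis cohort:", s$n_patients, "patients;",
      "matched per arm:", s$matched_per_arm, "\n")
  cat("  received predicted-optimal:",
      sprintf("%.1f%%", 100 * s$fraction_received_optimal), "\n")
  cat(sprintf("  outer-CV R^2 = %.3f", s$r2_cv))
  if (!is.na(s$permutation_p)) cat(sprintf(" (permutation p = %.3g)", s$permutation_p))
  cat("\n")
  sig <- x$sweep[!is.na(x$sweep$q) & x$sweep$q < 0.05, , drop = FALSE]
  if (nrow(sig)) {
    cat("  significant sweep thresholds (q < 0.05):",
        paste(sig$threshold, collapse = ", "), "\n")
  } else {
    cat("  no sweep threshold reaches q < 0.05\n")
  }
  invisible(x)
}

#' Run the pipeline on a patient subgroup
#'
#' Applies a row filter to the (loaded or simulated) cohort and reruns the
#' identical pipeline. If the filtered cohort is underpowered relative to
#' the full one, the minimum detectable effect size is logged as a warning
#' and recorded in the summary.
#'
#' @param config a [run_config()].
#' @param filter function taking the cohort data.frame and returning a
#'   logical row mask.
#' @param label subgroup label recorded in the report.
#' @return a `run_report` with `summary$subgroup` set.
#' @export
subgroup_run <- function(config, filter, label = "subgroup") {
  src <- resolve_cohort(config)
  mask <- filter(src$cohort)
  if (!any(mask)) stop("empty subgroup: filter '", label, "' selects no patients")
  sub <- src$cohort[mask, , drop = FALSE]
  truth <- if (!is.null(src$truth)) src$truth[mask, , drop = FALSE]
  arm_n <- table(sub$treatment)
  full_n <- min(table(src$cohort$treatment))
  mdd <- min_detectable_d(max(2L, min(arm_n)), max(2L, min(arm_n)))
  if (min(arm_n) < full_n) {
    warning("subgroup '", label, "' reduces power (",
            paste(arm_n, collapse = "/"),
            " per arm); minimum detectable d = ", round(mdd, 2))
  }
  cfg2 <- config
  cfg2$cohort <- sub
  report <- run_pipeline(cfg2)
  report$truth <- truth
  report$summary$subgroup <- label
  report$summary$min_detectable_d <- mdd
  report
}
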