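#' Configuration for the synthetic two-arm cohort simulator
#'
#' Builds the parameter set for [simulate_cohort()]. The simulator emulates a
#' naturalistic two-arm antidepressant cohort (electroconvulsive therapy vs
#' ketamine) in which treatment assignment is confounded by pretreatment
#' severity, the outcome is the minimum depressive-symptom score (min-QIDS,
#' integer 0--27) achieved during the acute course, and individualized
#' treatment effects arise from treatment-by-covariate interactions.
#'
#' Potential outcomes follow
#' \deqn{y(t) = \beta_0 + \sum_j \beta_j x_j + 1[t = ECT]\sum_j \gamma_j x_j + \epsilon,}
#' with \eqn{\epsilon \sim N(0, \sigma^2)} shared between arms, rounded half
#' away from zero and clipped to \[0, 27\]. \eqn{\beta} are the prognostic
#' (main-effect) coefficients, \eqn{\gamma} the prescriptive (interaction)
#' coefficients; lower outcomes are better, so a positive prescriptive sum
#' favors ketamine. Treatment is assigned by a logistic propensity model in
#' `confounding_coefs` (log-odds of receiving ECT); covariates are drawn
#' until each arm reaches `n_per_arm`, which preserves the covariate tilt
#' between arms that matching must then remove.
#'
#' The default prescriptive structure plants a strong binary prescriptive
#' marker (`sex`, ECT-disadvantage +4 QIDS points) and a baseline-severity
#' crossover (patients above roughly QIDS 17.5 do better with ECT, below it
#' with ketamine), so that at least half the cohort has a true advantage of
#' 2 or more QIDS points. Setting `prescriptive_coefs = NULL` (or an empty
#' vector) gives the null configuration in which no patient has a true
#' advantage.
#'
#' @param n_per_arm patients per treatment arm (>= 2).
#' @param seed integer seed; the whole draw is deterministic given it.
#' @param p_binary number of generic binary indicator predictors
#'   (`ind_001`...), emulating medication-history / comorbidity flags.
#' @param prevalence_range range the indicator prevalences are drawn from.
#' @param baseline_qids_mean,baseline_qids_sd pretreatment QIDS distribution
#'   (truncated to the inclusion range 10--27).
#' @param noise_sd outcome noise SD in QIDS points.
#' @param prognostic_coefs named numeric: main effects on the outcome
#'   (key `"(Intercept)"` allowed).
#' @param prescriptive_coefs named numeric: ECT-specific offsets (the
#'   simulated individualized treatment-effect components); `NULL` or empty
#'   for the null configuration.
#' @param confounding_coefs named numeric: log-odds effects on receiving ECT.
#' @param moca_missing_rate_by_arm named pair `c(ECT=, KET=)` of MCAR
#'   missingness rates for the MoCA score (cognitive screening is skipped
#'   far more often in one arm).
#' @param basis_missing_rate MCAR missingness rate for each BASIS-24
#'   subscale.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_per_arm = 235L,
                       seed = 1L,
                       p_binary = 20L,
                       prevalence_range = c(0.05, 0.5),
                       baseline_qids_mean = 17.6,
                       baseline_qids_sd = 3.4,
                       noise_sd = 2,
                       prognostic_coefs = c(
                         "(Intercept)" = -2.5,
                         qids_baseline = 0.55,
                         basis_self_harm = 1.0,
                         basis_psychosis = 0.6,
                         basis_emotional_lability = 0.4,
                         basis_relationships = 0.3,
                         basis_substance_abuse = 0.4,
                         age = 0.02,
                         inpatient = 1.0,
                         ind_001 = 0.8,
                         ind_002 = -0.6
                       ),
                       prescriptive_coefs = c(
                         "(Intercept)" = -6.125,
                         qids_baseline = 0.35,
                         sex = 4.0
                       ),
                       confounding_coefs = c(
                         "(Intercept)" = -2.8,
                         qids_baseline = 0.12,
                         inpatient = 0.9,
                         basis_psychosis = 0.5
                       ),
                       moca_missing_rate_by_arm = c(ECT = 0.02, KET = 0.29),
                       basis_missing_rate = 0.025) {
  if (is.null(prescriptive_coefs)) prescriptive_coefs <- numeric(0)
  cfg <- list(
    n_per_arm = as.integer(n_per_arm), seed = as.integer(seed),
    p_binary = as.integer(p_binary), prevalence_range = prevalence_range,
    baseline_qids_mean = baseline_qids_mean,
    baseline_qids_sd = baseline_qids_sd, noise_sd = noise_sd,
    prognostic_coefs = prognostic_coefs,
    prescriptive_coefs = prescriptive_coefs,
    confounding_coefs = confounding_coefs,
    moca_missing_rate_by_arm = moca_missing_rate_by_arm,
    basis_missing_rate = basis_missing_rate
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Null-configuration convenience wrapper
#'
#' Identical to [sim_config()] but with all prescriptive coefficients zero:
#' no patient has a true advantage from either arm, so any apparent
#' optimal/non-optimal outcome separation downstream is a false positive.
#'
#' @param ... passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_null <- function(...) {
  sim_config(prescriptive_coefs = NULL, ...)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_per_arm < 2L) stop("n_per_arm must be >= 2")
  rates <- c(cfg$moca_missing_rate_by_arm, cfg$basis_missing_rate,
             cfg$prevalence_range)
  if (any(rates < 0 | rates > 1)) stop("rates/prevalences must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(ARM_LEVELS %in% names(cfg$moca_missing_rate_by_arm))) {
    stop("moca_missing_rate_by_arm must be named with arms ", paste(ARM_LEVELS, collapse = ", "))
  }
  known <- c("(Intercept)", sim_predictor_names(cfg$p_binary))
  for (m in c("prognostic_coefs", "prescriptive_coefs", "confounding_coefs")) {
    bad <- setdiff(names(cfg[[m]]), known)
    if (length(bad)) {
      stop(m, " references undeclared predictor(s): ", paste(bad, collapse = ", "))
    }
  }
  invisible(cfg)
}

BASIS_COLS <- c("basis_relationships", "basis_self_harm",
                "basis_emotional_lability", "basis_psychosis",
                "basis_substance_abuse")

sim_predictor_names <- function(p_binary) {
  ind <- if (p_binary > 0) sprintf("ind_%03d", seq_len(p_binary)) else character(0)
  c("qids_baseline", BASIS_COLS, "moca", "age", "sex", "inpatient", ind)
}

# Draw a block of candidate patients' covariates. `prev` holds the fixed
# per-config indicator prevalences.
draw_covariates <- function(n, cfg, prev) {
  m <- cfg$baseline_qids_mean; s <- cfg$baseline_qids_sd
  u <- runif(n, pnorm(9.5, m, s), pnorm(27.49, m, s))
  df <- data.frame(
    qids_baseline = clip(round_half_away(qnorm(u, m, s)), 10, 27),
    basis_relationships = round(4 * stats::rbeta(n, 2, 2), 2),
    basis_self_harm = round(4 * stats::rbeta(n, 0.6, 3), 2),
    basis_emotional_lability = round(4 * stats::rbeta(n, 2, 2), 2),
    basis_psychosis = round(4 * stats::rbeta(n, 0.5, 4), 2),
    basis_substance_abuse = round(4 * stats::rbeta(n, 0.6, 3), 2),
    moca = clip(round_half_away(rnorm(n, 25.5, 3)), 0, 30),
    age = clip(round_half_away(rnorm(n, 43, 16)), 18, 90),
    sex = rbinom(n, 1, 0.58),
    inpatient = rbinom(n, 1, 0.3)
  )
  for (j in seq_len(cfg$p_binary)) {
    df[[sprintf("ind_%03d", j)]] <- rbinom(n, 1, prev[j])
  }
  df
}

#' Simulate a confounded two-arm cohort with ground truth
#'
#' Draws covariates, assigns treatment by the logistic propensity model,
#' computes both potential outcomes from the shared linear model plus noise,
#' observes the assigned arm's outcome, and injects missing-completely-at-
#' random values into MoCA (per arm) and the BASIS subscales. Patients are
#' drawn until each arm holds exactly `n_per_arm`, so within-arm covariate
#' distributions carry the planted confounding.
#'
#' @param config a [sim_config()].
#' @return a list of class `pai_sim` with elements
#'   \describe{
#'     \item{cohort}{data.frame: `patient_id`, `treatment` (factor ECT/KET),
#'       `min_qids`, and the predictor columns (with NAs where missing).}
#'     \item{truth}{data.frame keyed by `patient_id`: noise-free conditional
#'       means `mu_ect`/`mu_ket` (the true outcome functions), pre-rounding
#'       potential outcomes `y_ect_raw`/`y_ket_raw`, integer `y_ect`/`y_ket`,
#'       `propensity` (P(ECT | x)), `true_advantage`
#'       (|E\[y(ECT) - y(KET) | x\]|, QIDS points) and `true_optimal`
#'       (`"ECT"`, `"KET"` or `"indifferent"`).}
#'   }
#' @examples
#' sim <- simulate_cohort(sim_config(n_per_arm = 30, seed = 7))
#' table(sim$cohort$treatment)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  set.seed(spawn_seed(cfg$seed, "simulate"))
  prev <- runif(cfg$p_binary, cfg$prevalence_range[1], cfg$prevalence_range[2])

  need <- c(ECT = cfg$n_per_arm, KET = cfg$n_per_arm)
  got <- list(ECT = NULL, KET = NULL)
  guard <- 0L
  while (any(vapply(got, function(x) NROW(x), 0L) < need)) {
    guard <- guard + 1L
    if (guard > 1000L) stop("treatment assignment failed to fill both arms; check confounding_coefs")
    blk <- draw_covariates(2L * cfg$n_per_arm, cfg, prev)
    ps <- plogis(eval_linear(blk, cfg$confounding_coefs))
    arm <- ifelse(runif(nrow(blk)) < ps, "ECT", "KET")
    blk$.propensity <- ps
    for (a in ARM_LEVELS) {
      short <- need[[a]] - NROW(got[[a]])
      if (short > 0L) {
        rows <- blk[arm == a, , drop = FALSE]
        got[[a]] <- rbind(got[[a]], head(rows, short))
      }
    }
  }
  df <- rbind(got$ECT, got$KET)
  n <- nrow(df)
  treatment <- factor(rep(ARM_LEVELS, each = cfg$n_per_arm), levels = ARM_LEVELS)
  propensity <- df$.propensity
  df$.propensity <- NULL
  rownames(df) <- NULL

  mu_ket <- eval_linear(df, cfg$prognostic_coefs)
  tau <- eval_linear(df, cfg$prescriptive_coefs)   # ECT offset, QIDS points
  mu_ect <- mu_ket + tau
  eps <- rnorm(n, 0, cfg$noise_sd)
  y_ket_raw <- mu_ket + eps
  y_ect_raw <- mu_ect + eps
  y_ket <- clip(round_half_away(y_ket_raw), 0, 27)
  y_ect <- clip(round_half_away(y_ect_raw), 0, 27)
  min_qids <- ifelse(treatment == "ECT", y_ect, y_ket)

  patient_id <- sprintf("P%05d", seq_len(n))
  truth <- data.frame(
    patient_id = patient_id,
    mu_ect = mu_ect, mu_ket = mu_ket,
    y_ect_raw = y_ect_raw, y_ket_raw = y_ket_raw,
    y_ect = y_ect, y_ket = y_ket,
    propensity = propensity,
    true_advantage = abs(tau),
    true_optimal = ifelse(tau < 0, "ECT", ifelse(tau > 0, "KET", "indifferent")),
    stringsAsFactors = FALSE
  )

  cohort <- cbind(
    data.frame(patient_id = patient_id, treatment = treatment,
               min_qids = as.integer(min_qids), stringsAsFactors = FALSE),
    df
  )

  # MCAR missingness
  for (a in ARM_LEVELS) {
    r <- cfg$moca_missing_rate_by_arm[[a]]
    if (r > 0) {
      idx <- which(cohort$treatment == a)
      cohort$moca[idx[runif(length(idx)) < r]] <- NA
    }
  }
  if (cfg$basis_missing_rate > 0) {
    for (cl in BASIS_COLS) {
      cohort[[cl]][runif(n) < cfg$basis_missing_rate] <- NA
    }
  }

  structure(list(cohort = cohort, truth = truth, config = cfg),
            class = "pai_sim")
}

#' @export
print.pai_sim <- function(x, ...) {
  cat("Synthetic PAI cohort:", nrow(x$cohort), "patients (",
      paste(table(x$cohort$treatment), collapse = " + "), ")\n")
  cat("  mean true advantage:", round(mean(x$truth$true_advantage), 2),
      "QIDS points;", sum(x$truth$true_advantage >= 2), "patients >= 2\n")
  invisible(x)
}

cohort_mandatory_cols <- c("patient_id", "treatment", "min_qids", "qids_baseline")

#' Write / read a cohort table
#'
#' CSV round trip for the cohort schema. Missing values are written as empty
#' cells. On read the inclusion rule (pretreatment QIDS >= 10) is enforced:
#' offending rows are dropped with a reported count, mirroring how the study
#' cohort was assembled.
#'
#' @param cohort a cohort data.frame as produced by [simulate_cohort()].
#' @param path CSV file path.
#' @return `read_cohort()` returns the cohort data.frame with attribute
#'   `n_excluded` (rows dropped by the inclusion rule).
#' @export
write_cohort <- function(cohort, path) {
  check_cohort_schema(cohort)
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  check_cohort_schema(df)
  df$treatment <- factor(df$treatment, levels = ARM_LEVELS)
  bad <- which(df$qids_baseline < 10)
  if (length(bad)) {
    message(length(bad), " row(s) excluded: pretreatment QIDS below 10")
    df <- df[-bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "n_excluded") <- length(bad)
  df
}

check_cohort_schema <- function(df) {
  miss <- setdiff(cohort_mandatory_cols, names(df))
  if (length(miss)) stop("cohort is missing mandatory column(s): ", paste(miss, collapse = ", "))
  lev <- unique(as.character(df$treatment))
  if (length(lev) != 2L || !all(lev %in% ARM_LEVELS)) {
    stop("treatment must take exactly the two levels ", paste(ARM_LEVELS, collapse = "/"),
         "; found: ", paste(lev, collapse = ", "))
  }
  if (any(df$min_qids < 0 | df$min_qids > 27, na.rm = TRUE)) {
    stop("min_qids outside the 0-27 QIDS range")
  }
  invisible(df)
}

#' Predictor column names of a cohort
#'
#' Everything except the identifier and the outcome; the treatment column is
#' a predictor like any other (it is what gets flipped for counterfactual
#' prediction).
#'
#' @param cohort cohort data.frame.
#' @return character vector of predictor names, `treatment` first.
#' @export
predictor_columns <- function(cohort) {
  setdiff(names(cohort), c("patient_id", "min_qids"))
}
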