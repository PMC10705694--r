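#' Imputation rules
#'
#' Declares, per column, whether missing values are filled with the
#' within-stratum mode or mean. Strata default to the treatment arms:
#' distributions of pretreatment scales differ between arms, so donors come
#' from the same arm only. Skewed scales (MoCA, BASIS psychosis and
#' substance abuse) default to the mode; the more symmetric BASIS subscales
#' to the mean.
#'
#' @param strategies named character vector, values in `c("mode", "mean")`.
#' @param grouping column defining the imputation strata (default
#'   `"treatment"`).
#' @return an `imputation_rules` object.
#' @export
imputation_rules <- function(strategies = c(
                               moca = "mode",
                               basis_psychosis = "mode",
                               basis_substance_abuse = "mode",
                               basis_emotional_lability = "mean",
                               basis_relationships = "mean",
                               basis_self_harm = "mean"
                             ),
                             grouping = "treatment") {
  stopifnot(all(strategies %in% c("mode", "mean")), length(grouping) == 1L)
  structure(list(strategies = strategies, grouping = grouping),
            class = "imputation_rules")
}

# mode with ties broken by the smallest value
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)][1])  # table() sorts by value, so
                                             # which.max takes the smallest
                                             # of tied modes
}

#' Impute missing values within strata
#'
#' @param cohort cohort data.frame.
#' @param rules an [imputation_rules()] object; every column that actually
#'   contains missing values must have a declared strategy.
#' @return the cohort with no missing values in the declared columns.
#' @export
impute <- function(cohort, rules = imputation_rules()) {
  stopifnot(inherits(rules, "imputation_rules"))
  g <- cohort[[rules$grouping]]
  if (is.null(g)) stop("grouping column not found: ", rules$grouping)
  has_na <- names(cohort)[vapply(cohort, function(x) anyNA(x), TRUE)]
  undeclared <- setdiff(has_na, names(rules$strategies))
  if (length(undeclared)) {
    stop("missing values in column(s) without an imputation strategy: ",
         paste(undeclared, collapse = ", "))
  }
  for (cl in intersect(names(rules$strategies), names(cohort))) {
    if (!anyNA(cohort[[cl]])) next
    strat <- rules$strategies[[cl]]
    for (lev in unique(g)) {
      idx <- which(g == lev)
      vals <- cohort[[cl]][idx]
      nas <- is.na(vals)
      if (!any(nas)) next
      if (all(nas)) {
        stop("cannot impute '", cl, "': stratum '", lev, "' has no observed values")
      }
      fill <- if (strat == "mode") stat_mode(vals) else mean(vals, na.rm = TRUE)
      cohort[[cl]][idx[nas]] <- fill
    }
  }
  cohort
}

#' Near-zero-variance filter
#'
#' Drops feature columns with a single unique value, or whose ratio of the
#' most frequent to the second most frequent value count exceeds `freq_cut`
#' (default 19, i.e. worse than a 95:5 split). Exempt columns (the treatment
#' indicator, which counterfactual flipping requires) are always retained.
#'
#' @param feature_table data.frame or matrix of numeric/binary features.
#' @param freq_cut drop when most-frequent / second-most-frequent count is
#'   strictly greater than this ratio.
#' @param exempt column names never dropped.
#' @return character vector of retained column names, in original order.
#' @export
nzv_filter <- function(feature_table, freq_cut = 19, exempt = "treatment") {
  feature_table <- as.data.frame(feature_table)
  if (ncol(feature_table) == 0L || nrow(feature_table) == 0L) {
    stop("empty feature table")
  }
  keep <- vapply(names(feature_table), function(nm) {
    if (nm %in% exempt) return(TRUE)
    tab <- sort(table(feature_table[[nm]], useNA = "no"), decreasing = TRUE)
    if (length(tab) <= 1L) return(FALSE)
    (tab[1] / tab[2]) <= freq_cut
  }, TRUE)
  names(feature_table)[keep]
}

#' Propensity-score estimation
#'
#' Maximum-likelihood logistic regression of treatment (ECT = 1) on the
#' matching covariates.
#'
#' @param cohort cohort data.frame (both arms present).
#' @param covariates covariate column names; rows with missing values in
#'   these columns are not allowed here (exclude or impute first).
#' @return list with `propensity` (P(ECT | x)), `logit` scores and the
#'   fitted `model`.
#' @export
estimate_propensity <- function(cohort, covariates) {
  stopifnot(length(covariates) >= 1L)
  if (length(unique(cohort$treatment)) != 2L) stop("both arms must be present")
  dat <- cohort[, covariates, drop = FALSE]
  if (anyNA(dat)) stop("missing values in matching covariates; exclude or impute first")
  y <- as.integer(cohort$treatment == "ECT")
  # perfect separation would give degenerate, unmatchable scores: detect and
  # name the separating covariate
  for (v in covariates) {
    x1 <- dat[[v]][y == 1]; x0 <- dat[[v]][y == 0]
    if (max(x1) < min(x0) || max(x0) < min(x1)) {
      stop("perfect separation on covariate: ", v)
    }
  }
  fit <- suppressWarnings(glm(y ~ ., data = cbind(y = y, dat), family = binomial()))
  p <- as.numeric(fitted(fit))
  if (any(p < 1e-12) || any(p > 1 - 1e-12)) {
    stop("degenerate propensity fit (fitted probabilities at 0/1); check covariates for separation")
  }
  list(propensity = p, logit = qlogis_safe(p), model = fit)
}

qlogis_safe <- function(p) log(p / (1 - p))

#' 1:1 propensity-score matching
#'
#' Greedy nearest-neighbor matching without replacement on the logit of the
#' propensity score. Patients of the smaller arm are processed in an order
#' randomized by `seed`; each takes the closest unused patient of the other
#' arm, subject to an optional caliper expressed in standard deviations of
#' the logit scores. Without a caliper the smaller arm is matched in full.
#'
#' @param cohort cohort data.frame.
#' @param propensity per-patient P(ECT | x) as from [estimate_propensity()].
#' @param caliper maximum |logit difference| in SDs of the logit, or `NULL`
#'   for none.
#' @param covariates covariate names for the balance diagnostics (defaults
#'   to every numeric predictor present).
#' @param seed integer seed for the processing order.
#' @return a `match_result` list: `pairs` (data.frame treated_id/control_id,
#'   treated = ECT), `matched_ids`, `excluded_ids`, `propensity`, `logit`,
#'   and per-covariate `smd_before` / `smd_after` (standardized mean
#'   differences, denominator from the pre-matching sample).
#' @export
match_1to1 <- function(cohort, propensity, caliper = NULL,
                       covariates = NULL, seed = 1L) {
  stopifnot(length(propensity) == nrow(cohort))
  lg <- qlogis_safe(propensity)
  id <- cohort$patient_id
  i_t <- which(cohort$treatment == "ECT")
  i_c <- which(cohort$treatment == "KET")
  small_is_t <- length(i_t) <= length(i_c)
  small <- if (small_is_t) i_t else i_c
  big <- if (small_is_t) i_c else i_t
  cal <- if (is.null(caliper)) Inf else caliper * sd(lg)

  set.seed(spawn_seed(seed, "match"))
  ord <- sample(small)
  used <- logical(length(big))
  pairs <- matrix(NA_integer_, nrow = 0, ncol = 2)
  for (i in ord) {
    d <- abs(lg[big] - lg[i])
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= cal) {
      used[j] <- TRUE
      pairs <- rbind(pairs, c(i, big[j]))
    }
  }
  if (nrow(pairs) == 0L) stop("caliper too tight: no pairs formed")
  t_rows <- if (small_is_t) pairs[, 1] else pairs[, 2]
  c_rows <- if (small_is_t) pairs[, 2] else pairs[, 1]
  matched <- sort(c(t_rows, c_rows))

  if (is.null(covariates)) {
    covariates <- Filter(function(v) is.numeric(cohort[[v]]),
                         setdiff(names(cohort), c("patient_id", "treatment", "min_qids")))
  }
  smd <- function(rows_t, rows_c) {
    vapply(covariates, function(v) {
      xt <- cohort[[v]][i_t]; xc <- cohort[[v]][i_c]   # pre-matching SDs
      den <- sqrt((var(xt, na.rm = TRUE) + var(xc, na.rm = TRUE)) / 2)
      num <- mean(cohort[[v]][rows_t], na.rm = TRUE) -
             mean(cohort[[v]][rows_c], na.rm = TRUE)
      if (isTRUE(den > 0)) num / den else ifelse(num == 0, 0, NA_real_)
    }, 0)
  }
  structure(list(
    pairs = data.frame(treated_id = id[t_rows], control_id = id[c_rows],
                       stringsAsFactors = FALSE),
    matched_ids = id[matched],
    excluded_ids = id[setdiff(seq_len(nrow(cohort)), matched)],
    propensity = setNames(propensity, id),
    logit = setNames(lg, id),
    smd_before = smd(i_t, i_c),
    smd_after = smd(t_rows, c_rows)
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("1:1 propensity match:", nrow(x$pairs), "pairs;",
      length(x$excluded_ids), "patients unmatched\n")
  cat("  mean |SMD| before:", round(mean(abs(x$smd_before), na.rm = TRUE), 3),
      " after:", round(mean(abs(x$smd_after), na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Between-arm comparison table
#'
#' Welch t-tests for continuous variables and chi-squared tests (2x2 with
#' continuity correction) for binary/categorical variables, one row per
#' variable — the standard baseline-characteristics comparison.
#'
#' @param cohort cohort data.frame.
#' @param variables columns to compare (default: all predictors except
#'   treatment).
#' @return data.frame with columns `variable`, `test` ("t" or "chi2"),
#'   `statistic`, `p`, `significant` (p < 0.05). Zero-variance continuous
#'   variables carry `NA` statistics.
#' @export
compare_arms <- function(cohort, variables = NULL) {
  if (length(unique(cohort$treatment)) != 2L) stop("two arms required")
  if (is.null(variables)) {
    variables <- setdiff(names(cohort), c("patient_id", "treatment"))
  }
  g <- cohort$treatment
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    vals <- unique(x[!is.na(x)])
    binaryish <- is.character(x) || is.factor(x) || length(vals) <= 2L
    if (binaryish) {
      tab <- table(x, g)
      res <- tryCatch(suppressWarnings(chisq.test(tab, correct = TRUE)),
                      error = function(e) NULL)
      stat <- if (is.null(res)) NA_real_ else unname(res$statistic)
      p <- if (is.null(res)) NA_real_ else res$p.value
      data.frame(variable = v, test = "chi2", statistic = stat, p = p,
                 stringsAsFactors = FALSE)
    } else {
      a <- x[g == "ECT"]; b <- x[g == "KET"]
      wt <- welch_t(a[!is.na(a)], b[!is.na(b)])
      data.frame(variable = v, test = "t", statistic = wt$t, p = wt$p_two,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < 0.05
  out
}

# Welch two-sample t; returns statistic, df, one-sided (less) and two-sided p.
# Zero variance in both groups: t = 0 / p = 0.5 when means agree (no evidence
# either way), +/-Inf otherwise.
welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  dm <- mean(a) - mean(b)
  if (se2 == 0) {
    if (dm == 0) return(list(t = 0, df = na + nb - 2, p_less = 0.5, p_two = 1))
    t <- sign(dm) * Inf
    return(list(t = t, df = na + nb - 2,
                p_less = ifelse(dm < 0, 0, 1), p_two = 0))
  }
  t <- dm / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  list(t = t, df = df, p_less = pt(t, df), p_two = 2 * pt(-abs(t), df))
}
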