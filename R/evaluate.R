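#' Coefficient of determination (sum-of-squares form)
#'
#' \eqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2}; the fraction of
#' outcome variance captured by the predictions. Can be negative for models
#' worse than the mean predictor.
#'
#' @param y observed outcomes (variance > 0, length >= 2).
#' @param yhat predictions.
#' @return R-squared.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("outcome has zero variance; R^2 undefined")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Permutation test of model fit
#'
#' Assesses the significance of the observed R-squared by re-running the
#' entire modeling procedure on outcome-permuted data: the outcome column is
#' reshuffled across patients (treatment and covariates untouched) and the
#' full pipeline — including any embedded tuning — is repeated, B times.
#' The p-value uses the add-one convention
#' \eqn{p = (1 + \#\{R^2_{perm} \ge R^2_{obs}\}) / (B + 1)}, so it can
#' never be exactly zero at finite B.
#'
#' @param pipeline_runner `function(cohort, seed)` returning either a single
#'   R-squared or a list with elements `y` and `yhat`.
#' @param cohort the analysis cohort.
#' @param B number of permutations (study value 1000; desk default 99).
#' @param seed integer seed.
#' @param max_redraws failed permutation replicates are logged and redrawn,
#'   at most this many times in total.
#' @return an `eval_result` list: `r2`, `permutation_p`, `b_used`,
#'   `permuted_r2`, `n_failed`.
#' @export
permutation_test <- function(pipeline_runner, cohort, B = 99L, seed = 1L,
                             max_redraws = 10L) {
  stopifnot(B >= 1L)
  as_r2 <- function(res) {
    if (is.list(res)) r_squared(res$y, res$yhat) else as.numeric(res)
  }
  r2_obs <- as_r2(pipeline_runner(cohort, spawn_seed(seed, "perm_obs")))

  permuted <- numeric(0)
  n_failed <- 0L
  i <- 0L
  while (length(permuted) < B) {
    i <- i + 1L
    if (i > B + max_redraws) stop("too many failed permutation replicates")
    set.seed(spawn_seed(seed, "perm_shuffle", i))
    shuffled <- cohort
    shuffled$min_qids <- cohort$min_qids[sample.int(nrow(cohort))]
    res <- tryCatch(as_r2(pipeline_runner(shuffled, spawn_seed(seed, "perm_run", i))),
                    error = function(e) {
                      message("permutation replicate ", i, " failed: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) n_failed <- n_failed + 1L else permuted <- c(permuted, res)
  }
  p <- (1 + sum(permuted >= r2_obs)) / (B + 1)
  structure(list(r2 = r2_obs, permutation_p = p, b_used = B,
                 permuted_r2 = permuted, n_failed = n_failed),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("R^2 = %.4f, permutation p = %.4g (B = %d)\n",
              x$r2, x$permutation_p, x$b_used))
  invisible(x)
}

#' Minimum detectable effect size for a two-sample t-test
#'
#' Smallest Cohen's d at which a two-sample t-test attains the target power
#' at significance level `alpha`, solved by bisection on the noncentral t
#' distribution (noncentrality \eqn{d\sqrt{n_1 n_2/(n_1+n_2)}}, df
#' \eqn{n_1+n_2-2}) to 1e-6.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param alpha significance level.
#' @param power target power in (0, 1).
#' @param one_sided one-sided test (the study's configuration) or
#'   two-sided.
#' @return minimum detectable d.
#' @export
min_detectable_d <- function(n1, n2, alpha = 0.05, power = 0.80,
                             one_sided = TRUE) {
  stopifnot(n1 >= 2L, n2 >= 2L)
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  df <- n1 + n2 - 2
  crit <- if (one_sided) qt(1 - alpha, df) else qt(1 - alpha / 2, df)
  pow <- function(d) {
    ncp <- d * sqrt(n1 * n2 / (n1 + n2))
    if (one_sided) {
      1 - pt(crit, df, ncp = ncp)
    } else {
      1 - pt(crit, df, ncp = ncp) + pt(-crit, df, ncp = ncp)
    }
  }
  lo <- 0; hi <- 10
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (pow(mid) < power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
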