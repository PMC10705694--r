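#' Random-forest regression parameters
#'
#' @param n_trees number of regression trees (study default 1000).
#' @param mtry candidate split variables per node; `NULL` for ranger's
#'   default (floor(sqrt(p))).
#' @param splitrule `"variance"` or `"extratrees"`.
#' @param min_node_size minimum node size to allow a further split.
#' @param max_depth optional cap on tree depth (`NULL` = unlimited).
#' @param seed integer seed; fits are deterministic given it (single
#'   thread).
#' @return an `rf_params` list.
#' @export
rf_params <- function(n_trees = 1000L, mtry = NULL, splitrule = "variance",
                      min_node_size = 5L, max_depth = NULL, seed = 1L) {
  stopifnot(splitrule %in% c("variance", "extratrees"),
            min_node_size >= 1L, n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 splitrule = splitrule,
                 min_node_size = as.integer(min_node_size),
                 max_depth = max_depth,
                 seed = as.integer(seed)),
            class = "rf_params")
}

#' Fit a random-forest regression model
#'
#' Thin wrapper over [ranger::ranger()] keeping the training matrix and
#' in-bag counts, which the tree-SHAP machinery needs to compute node
#' covers.
#'
#' @param X data.frame of numeric features (no missing values).
#' @param y numeric outcome.
#' @param params an [rf_params()] object.
#' @return a `pai_rfr` model object with a [predict()] method.
#' @export
fit_rfr <- function(X, y, params = rf_params()) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) >= 2L, nrow(X) == length(y), !anyNA(X), !anyNA(y))
  p <- ncol(X)
  mtry <- params$mtry
  if (is.null(mtry) || is.na(mtry)) mtry <- NULL   # ranger default floor(sqrt(p))
  if (!is.null(mtry) && mtry > p) {
    stop("mtry (", mtry, ") exceeds the number of features (", p, ")")
  }
  dat <- cbind(X, .outcome = y)
  rf <- ranger::ranger(
    dependent.variable.name = ".outcome", data = dat,
    num.trees = params$n_trees, mtry = mtry,
    splitrule = params$splitrule, min.node.size = params$min_node_size,
    max.depth = params$max_depth,
    seed = params$seed, num.threads = 1L, keep.inbag = TRUE,
    respect.unordered.factors = "ignore"
  )
  structure(list(rf = rf, features = names(X), params = params,
                 X_train = X, y_train = y,
                 cache = new.env(parent = emptyenv())),
            class = "pai_rfr")
}

#' @param object,newdata standard predict arguments; `newdata` must contain
#'   the training feature columns.
#' @param ... unused.
#' @rdname fit_rfr
#' @export
predict.pai_rfr <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$features, drop = FALSE]
  predict(object$rf, data = newdata, num.threads = 1L)$predictions
}

#' @export
print.pai_rfr <- function(x, ...) {
  cat("Random-forest regression:", x$params$n_trees, "trees,",
      length(x$features), "features, splitrule", x$params$splitrule, "\n")
  invisible(x)
}

#' Permutation importance
#'
#' Mean increase in mean-squared error when a feature column is permuted,
#' over `n_repeats` seeded permutations. A feature no tree uses scores
#' exactly zero.
#'
#' @param model a fitted `pai_rfr`.
#' @param X,y evaluation data (typically the training data).
#' @param n_repeats permutations per feature.
#' @param seed integer seed.
#' @return named numeric vector of importance scores.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 5L, seed = 1L) {
  stopifnot(inherits(model, "pai_rfr"), n_repeats >= 1L)
  X <- as.data.frame(X)
  base <- mean((y - predict(model, X))^2)
  set.seed(spawn_seed(seed, "perm_importance"))
  n <- nrow(X)
  scores <- vapply(model$features, function(v) {
    mean(vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[[v]] <- Xp[[v]][sample.int(n)]
      mean((y - predict(model, Xp))^2) - base
    }, 0))
  }, 0)
  scores
}

#' Importance-based feature selection
#'
#' Retains the top-ranked features: `k = min(#positive importances,
#' ceil(fraction * p))`, falling back to the top `ceil(fraction * p)`
#' regardless of sign when no importance is positive. The treatment column
#' is excluded from the ranking and always appended — counterfactual
#' flipping is meaningless if the learner discards it.
#'
#' @param importances named importance vector (may include the treatment
#'   column; it is ignored for ranking).
#' @param fraction upper fraction of features retained (default 0.70).
#' @param treatment_col name of the treatment indicator.
#' @return character vector of retained feature names (treatment last).
#' @export
select_features <- function(importances, fraction = 0.70,
                            treatment_col = "treatment") {
  imp <- importances[setdiff(names(importances), treatment_col)]
  p <- length(imp)
  if (p == 0L) return(treatment_col)
  k_cap <- ceiling(fraction * p)
  k <- min(sum(imp > 0), k_cap)
  if (k == 0L) k <- k_cap
  ord <- order(-imp, seq_along(imp))   # ties: earlier column wins
  c(names(imp)[ord[seq_len(k)]], treatment_col)
}

#' Tuning grid for the nested cross-validation
#'
#' @param mtry,splitrule,min_node_size,n_filter candidate vectors;
#'   `n_filter = NA` means "use the importance rule's own k"
#'   ([select_features()]).
#' @param inner_k inner folds (default 10).
#' @return a `tuning_grid` object.
#' @export
tuning_grid <- function(mtry = NULL, splitrule = c("variance", "extratrees"),
                        min_node_size = c(5L, 10L, 20L), n_filter = NA,
                        inner_k = 10L) {
  structure(list(mtry = mtry, splitrule = splitrule,
                 min_node_size = as.integer(min_node_size),
                 n_filter = n_filter, inner_k = as.integer(inner_k)),
            class = "tuning_grid")
}

#' Minimal single-point grid
#'
#' One candidate combination (no inner grid search): variance splitrule,
#' `mtry = floor(p/3)`, `min_node_size = 5`, importance-rule feature count.
#' Appropriate for replicate-heavy simulation studies where the tuning
#' search itself is not under test.
#'
#' @param inner_k inner folds.
#' @return a `tuning_grid`.
#' @export
minimal_grid <- function(inner_k = 10L) {
  tuning_grid(mtry = NA_integer_, splitrule = "variance", min_node_size = 5L,
              n_filter = NA, inner_k = inner_k)
}

expand_tuning_grid <- function(grid, p) {
  mtry <- grid$mtry %||% unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3), floor(p / 2))))
  expand.grid(mtry = mtry, splitrule = grid$splitrule,
              min_node_size = grid$min_node_size, n_filter = grid$n_filter,
              stringsAsFactors = FALSE)
}

make_folds <- function(n, k, seed) {
  set.seed(spawn_seed(seed, "folds"))
  sample(rep_len(seq_len(k), n))
}

#' Nested cross-validation training
#'
#' The embedded model-building procedure, applied to training data only:
#' (1) near-zero-variance filter; (2) feature ranking by permutation
#' importance from a forest fit to the training data; (3) inner k-fold
#' cross-validation over the parameter grid (mtry, splitrule,
#' min_node_size, n_filter), scored by mean held-fold RMSE; (4) refit on
#' all training data with the winning parameters and retained features. The
#' treatment indicator survives every step. With a single grid point the
#' inner loop is skipped (the winner is forced).
#'
#' @param X training features including the treatment column (no missing
#'   values).
#' @param y training outcomes.
#' @param grid a [tuning_grid()].
#' @param seed integer seed driving fold assignment and all forest fits.
#' @param n_trees trees per forest.
#' @param importance_repeats permutations per feature for the ranking step.
#' @param treatment_col treatment indicator name.
#' @return a `tuned_model` list: `model` (final `pai_rfr`), `params`
#'   (winning row), `features` (retained names), `cv_scores` (grid with
#'   inner RMSE), `importance`.
#' @export
nested_cv_train <- function(X, y, grid = tuning_grid(), seed = 1L,
                            n_trees = 1000L, importance_repeats = 3L,
                            treatment_col = "treatment") {
  X <- as.data.frame(X)
  stopifnot(inherits(grid, "tuning_grid"), nrow(X) >= 2L * grid$inner_k)

  keep <- nzv_filter(X, exempt = treatment_col)
  Xf <- X[, keep, drop = FALSE]
  p_rank <- ncol(Xf)

  rank_fit <- fit_rfr(Xf, y, rf_params(n_trees = n_trees, splitrule = "variance",
                                       min_node_size = 5L,
                                       seed = spawn_seed(seed, "rank_forest")))
  imp <- permutation_importance(rank_fit, Xf, y, n_repeats = importance_repeats,
                                seed = spawn_seed(seed, "rank_importance"))
  sel_default <- select_features(imp, treatment_col = treatment_col)

  cand <- expand_tuning_grid(grid, p_rank)
  feats_for <- function(n_filter) {
    if (is.na(n_filter)) return(sel_default)
    imp_nt <- imp[setdiff(names(imp), treatment_col)]
    k <- min(as.integer(n_filter), length(imp_nt))
    ord <- order(-imp_nt, seq_along(imp_nt))
    c(names(imp_nt)[ord[seq_len(k)]], treatment_col)
  }

  if (nrow(cand) > 1L) {
    folds <- make_folds(nrow(Xf), grid$inner_k, spawn_seed(seed, "inner_folds"))
    score <- rep(NA_real_, nrow(cand))
    for (ci in seq_len(nrow(cand))) {
      feats <- feats_for(cand$n_filter[ci])
      if (!is.na(cand$mtry[ci]) && cand$mtry[ci] > length(feats)) next   # skipped, logged via NA
      rmse <- vapply(seq_len(grid$inner_k), function(f) {
        tr <- folds != f
        fit <- fit_rfr(Xf[tr, feats, drop = FALSE], y[tr],
                       rf_params(n_trees = n_trees, mtry = cand$mtry[ci],
                                 splitrule = cand$splitrule[ci],
                                 min_node_size = cand$min_node_size[ci],
                                 seed = spawn_seed(seed, "inner_fit", ci * 1000L + f)))
        sqrt(mean((y[!tr] - predict(fit, Xf[!tr, , drop = FALSE]))^2))
      }, 0)
      score[ci] <- mean(rmse)
    }
    if (all(is.na(score))) stop("every grid point was skipped (mtry exceeds the feature count)")
    best <- which.min(score)
  } else {
    score <- NA_real_
    best <- 1L
    if (!is.na(cand$mtry[1]) && cand$mtry[1] > length(feats_for(cand$n_filter[1]))) {
      stop("every grid point was skipped (mtry exceeds the feature count)")
    }
  }

  feats <- feats_for(cand$n_filter[best])
  final <- fit_rfr(Xf[, feats, drop = FALSE], y,
                   rf_params(n_trees = n_trees, mtry = cand$mtry[best],
                             splitrule = cand$splitrule[best],
                             min_node_size = cand$min_node_size[best],
                             seed = spawn_seed(seed, "final_fit")))
  structure(list(model = final, params = cand[best, , drop = FALSE],
                 features = feats,
                 cv_scores = cbind(cand, inner_rmse = score),
                 importance = imp),
            class = "tuned_model")
}

#' @export
print.tuned_model <- function(x, ...) {
  cat("Tuned RFR:", length(x$features), "features;",
      "mtry =", if (is.na(x$params$mtry)) "default" else x$params$mtry,
      "splitrule =", x$params$splitrule,
      "min_node_size =", x$params$min_node_size, "\n")
  invisible(x)
}
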