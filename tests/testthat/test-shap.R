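test_that("single-feature models put the whole deviation on that feature", {
  set.seed(1)
  X <- data.frame(x1 = rnorm(80))
  y <- X$x1
  m <- fit_rfr(X, y, rf_params(n_trees = 30, min_node_size = 5, seed = 1))
  ex <- shap_values(m)
  expect_equal(ex$phi[, "x1"], ex$pred - ex$baseline, tolerance = 1e-10)
})

test_that("attributions and interactions match exhaustive Shapley enumeration", {
  set.seed(5)
  worst_phi <- 0; worst_int <- 0; worst_acc <- 0
  for (rep in 1:8) {
    n <- 50
    p <- sample(3:5, 1)
    X <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(X) <- paste0("x", seq_len(p))
    y <- 2 * X$x1 + X$x2 * X$x3 + rnorm(n, 0, 0.3)
    m <- fit_rfr(X, y, rf_params(n_trees = 8, min_node_size = 10, seed = rep))
    ex <- shap_interactions(m, X[1:5, ])
    forest <- shap_forest(m)
    for (i in 1:5) {
      x <- as.numeric(X[i, ])
      worst_phi <- max(worst_phi, max(abs(shap_brute(forest, x, p) - ex$phi[i, ])))
      worst_int <- max(worst_int, max(abs(inter_brute(forest, x, p) - ex$interaction[i, , ])))
      worst_acc <- max(worst_acc,
                       abs(ex$baseline + sum(ex$phi[i, ]) - ex$pred[i]))
    }
  }
  expect_lt(worst_phi, 1e-6)
  expect_lt(worst_int, 1e-6)
  expect_lt(worst_acc, 1e-6)
})

test_that("additive ensembles have zero off-diagonal interaction mass", {
  # tree A uses only x1, tree B only x2: a purely additive two-tree ensemble
  stump <- function(feat, lo, hi) {
    list(left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
         feature = c(feat, -1L, -1L), threshold = c(0, 0, 0),
         value = c(0, lo, hi), cover = c(10, 5, 5))
  }
  forest <- structure(list(stump(0L, -1, 1), stump(1L, -2, 2)),
                      class = "shap_forest", features = c("x1", "x2"))
  Xm <- matrix(c(-0.5, 0.7, 1.2, -2, 0.3, 0.4), ncol = 2, byrow = TRUE)
  phi <- pairf:::cpp_forest_shap(forest, Xm, 2L)
  inter <- pairf:::forest_shap_interactions(forest, Xm, phi)
  expect_lt(max(abs(inter[, 1, 2])), 1e-12)
  expect_lt(max(abs(inter[, 2, 1])), 1e-12)
  for (i in 1:3) {
    expect_equal(inter[i, , ], inter_brute(forest, Xm[i, ], 2), tolerance = 1e-10, ignore_attr = TRUE)
  }

  # f = sign(x1 * x2) as one depth-2 tree: real off-diagonal mass, matching
  # the exhaustive pairwise enumeration
  xor_tree <- list(
    left = c(1L, 3L, 5L, -1L, -1L, -1L, -1L),
    right = c(2L, 4L, 6L, -1L, -1L, -1L, -1L),
    feature = c(0L, 1L, 1L, -1L, -1L, -1L, -1L),
    threshold = c(0, 0, 0, 0, 0, 0, 0),
    value = c(0, 0, 0, 1, -1, -1, 1),
    cover = c(8, 4, 4, 2, 2, 2, 2)
  )
  forest2 <- structure(list(xor_tree), class = "shap_forest",
                       features = c("x1", "x2"))
  phi2 <- pairf:::cpp_forest_shap(forest2, Xm, 2L)
  inter2 <- pairf:::forest_shap_interactions(forest2, Xm, phi2)
  expect_gt(max(abs(inter2[, 1, 2])), 0.1)
  for (i in 1:3) {
    expect_equal(phi2[i, ], shap_brute(forest2, Xm[i, ], 2), tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(inter2[i, , ], inter_brute(forest2, Xm[i, ], 2), tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("interaction identities hold: symmetry and row sums", {
  sim <- tiny_cohort(n_per_arm = 25, seed = 12)
  co <- impute(sim$cohort)
  X <- pairf:::build_feature_table(co)
  m <- fit_rfr(X, co$min_qids, rf_params(n_trees = 40, seed = 3))
  ex <- shap_interactions(m, X[1:15, ])
  for (i in 1:15) {
    M <- ex$interaction[i, , ]
    expect_lt(max(abs(M - t(M))), 1e-6)
    expect_lt(max(abs(rowSums(M) - ex$phi[i, ])), 1e-6)
  }
  expect_lt(max(abs(ex$baseline + rowSums(ex$phi) - ex$pred)), 1e-6)
})

test_that("global importance ranks planted signal and ignores dead features", {
  set.seed(21)
  n <- 100
  X <- data.frame(strong = rnorm(n), weak = rnorm(n), dead = rep(1, n))
  y <- 5 * X$strong + 0.3 * X$weak + rnorm(n, 0, 0.3)
  m <- fit_rfr(X, y, rf_params(n_trees = 60, seed = 21))
  ex <- shap_values(m)
  gi <- global_importance(ex)
  expect_equal(gi$feature[1], "strong")
  expect_equal(gi$importance[gi$feature == "dead"], 0)
  expect_equal(gi$feature[3], "dead")

  # invariant to patient order
  ex2 <- shap_values(m, X[n:1, ])
  expect_equal(global_importance(ex2)$importance, gi$importance,
               tolerance = 1e-12)

  # dominant feature ranks first across seeds
  hits <- 0L
  for (s in 1:10) {
    set.seed(300 + s)
    Xs <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
    ys <- 4 * Xs$a + 0.5 * Xs$b + rnorm(60, 0, 0.5)
    ms <- fit_rfr(Xs, ys, rf_params(n_trees = 50, seed = s))
    if (global_importance(shap_values(ms))$feature[1] == "a") hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("duplicated identical features share credit symmetrically", {
  set.seed(8)
  n <- 120
  X <- data.frame(x = rnorm(n))
  X$x_copy <- X$x
  y <- 3 * X$x + rnorm(n, 0, 0.2)
  # average over seeds: per-seed splits break ties arbitrarily, in
  # expectation the twins earn equal mean |phi|
  imp <- replicate(10, {
    m <- fit_rfr(X, y, rf_params(n_trees = 40, seed = sample.int(1e6, 1)))
    colMeans(abs(shap_values(m)$phi))
  })
  means <- rowMeans(imp)
  expect_lt(abs(means["x"] - means["x_copy"]) / mean(means), 0.1)
})

test_that("prescriptive profiles expose the planted treatment interaction", {
  hits <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    sim <- simulate_cohort(sim_config(
      n_per_arm = 80, seed = 500 + s, p_binary = 2, noise_sd = 1,
      moca_missing_rate_by_arm = c(ECT = 0, KET = 0), basis_missing_rate = 0
    ))
    co <- sim$cohort
    X <- pairf:::build_feature_table(co)
    m <- fit_rfr(X, co$min_qids, rf_params(n_trees = 100, seed = s))
    ex <- shap_interactions(m, X[seq(1, nrow(X), by = 2), ])
    prof <- prescriptive_profile(ex, "sex")
    ss <- attr(prof, "sign_summary")
    # planted effect: ECT is harmful for sex = 1 (offset +4), so the high
    # side should favor KET
    if (identical(ss$favored_arm[ss$side == "high"], "KET")) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("null simulations carry less treatment-interaction mass than planted ones", {
  mass <- function(cfg) {
    sim <- simulate_cohort(cfg)
    co <- sim$cohort
    X <- pairf:::build_feature_table(co)
    m <- fit_rfr(X, co$min_qids, rf_params(n_trees = 80, seed = 1))
    ex <- shap_interactions(m, X[1:60, ])
    tr_idx <- which(colnames(ex$phi) == "treatment")
    mean(abs(ex$interaction[, , tr_idx][, -tr_idx]))
  }
  args <- list(n_per_arm = 80, seed = 42, p_binary = 2, noise_sd = 1,
               moca_missing_rate_by_arm = c(ECT = 0, KET = 0),
               basis_missing_rate = 0)
  planted <- mass(do.call(sim_config, args))
  null <- mass(do.call(sim_config_null, args))
  expect_lt(null, planted)
})

test_that("prescriptive-profile edge cases error cleanly", {
  sim <- tiny_cohort(n_per_arm = 10, seed = 4)
  co <- impute(sim$cohort)
  X <- pairf:::build_feature_table(co)
  m <- fit_rfr(X, co$min_qids, rf_params(n_trees = 10, seed = 1))
  ex_nointer <- shap_values(m)
  expect_error(prescriptive_profile(ex_nointer, "age"), "no interaction")
  ex <- shap_interactions(m, X[1:5, ])
  expect_error(prescriptive_profile(ex, "treatment"), "itself")
  expect_error(prescriptive_profile(ex, "not_there"), "not in the model")
})

test_that("waterfall tables run from baseline to prediction exactly", {
  sim <- tiny_cohort(n_per_arm = 15, seed = 6)
  co <- impute(sim$cohort)
  X <- pairf:::build_feature_table(co)
  m <- fit_rfr(X, co$min_qids, rf_params(n_trees = 25, seed = 2))
  ex <- shap_values(m, X, patient_id = co$patient_id)

  pid <- co$patient_id[3]
  wf_all <- waterfall(ex, pid, top_k = ncol(ex$phi))
  expect_equal(wf_all$cumulative[nrow(wf_all)], attr(wf_all, "prediction"),
               tolerance = 1e-6)
  expect_false("other" %in% wf_all$feature)

  wf0 <- waterfall(ex, pid, top_k = 0)
  expect_equal(nrow(wf0), 1L)
  expect_equal(wf0$feature, "other")
  expect_equal(wf0$phi, attr(wf0, "prediction") - attr(wf0, "baseline"),
               tolerance = 1e-6)

  wf3 <- waterfall(ex, pid, top_k = 3)
  phi <- ex$phi[3, ]
  expect_equal(wf3$feature[1:3],
               colnames(ex$phi)[order(-abs(phi), seq_along(phi))][1:3])
  expect_true(all(diff(abs(wf3$phi[1:3])) <= 1e-12))

  expect_error(waterfall(ex, "nope"), "unknown patient_id")
})
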