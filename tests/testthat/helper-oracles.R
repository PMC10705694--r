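# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (enumeration, closed form, or brute force) kept separate from
# the implementation it checks.

# --- Benjamini-Hochberg by the step-up definition -------------------------
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- rep(NA_real_, m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[ord[i]] / i)
    q[ord[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# --- near-zero variance by direct frequency counting ----------------------
nzv_brute <- function(df, freq_cut = 19, exempt = "treatment") {
  keep <- character(0)
  for (nm in names(df)) {
    if (nm %in% exempt) { keep <- c(keep, nm); next }
    cnt <- sort(table(df[[nm]]), decreasing = TRUE)
    if (length(cnt) == 1) next
    if (cnt[[1]] / cnt[[2]] > freq_cut) next
    keep <- c(keep, nm)
  }
  keep
}

# --- feature-retention rule re-derived line by line -----------------------
select_brute <- function(imp, fraction = 0.7, treatment_col = "treatment") {
  imp <- imp[names(imp) != treatment_col]
  p <- length(imp)
  cap <- ceiling(fraction * p)
  k <- min(sum(imp > 0), cap)
  if (k == 0) k <- cap
  ranked <- names(imp)[order(-imp, seq_len(p))]
  c(ranked[1:k], treatment_col)
}

# --- path-dependent expectation of a tree for a feature subset ------------
tree_expect <- function(tree, x, S, node = 1L) {
  if (tree$left[node] < 0) return(tree$value[node])
  f <- tree$feature[node] + 1L
  le <- tree$left[node] + 1L
  ri <- tree$right[node] + 1L
  if (f %in% S) {
    if (x[f] <= tree$threshold[node]) tree_expect(tree, x, S, le)
    else tree_expect(tree, x, S, ri)
  } else {
    (tree$cover[le] * tree_expect(tree, x, S, le) +
       tree$cover[ri] * tree_expect(tree, x, S, ri)) / tree$cover[node]
  }
}

forest_expect <- function(forest, x, S) {
  mean(vapply(forest, tree_expect, 0, x = x, S = S))
}

all_subsets <- function(v) {
  out <- list(integer(0))
  for (k in seq_along(v)) out <- c(out, combn(v, k, simplify = FALSE))
  out
}

# exhaustive Shapley values over all 2^p subsets
shap_brute <- function(forest, x, p) {
  phi <- numeric(p)
  for (j in seq_len(p)) {
    for (S in all_subsets(setdiff(seq_len(p), j))) {
      k <- length(S)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      phi[j] <- phi[j] +
        w * (forest_expect(forest, x, c(S, j)) - forest_expect(forest, x, S))
    }
  }
  phi
}

# exhaustive Shapley interaction index (off-diagonals), diagonal from the
# row-sum identity
inter_brute <- function(forest, x, p) {
  I <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) if (i < j) {
    tot <- 0
    for (S in all_subsets(setdiff(seq_len(p), c(i, j)))) {
      k <- length(S)
      w <- factorial(k) * factorial(p - k - 2) / (2 * factorial(p - 1))
      tot <- tot + w *
        (forest_expect(forest, x, c(S, i, j)) - forest_expect(forest, x, c(S, i)) -
           forest_expect(forest, x, c(S, j)) + forest_expect(forest, x, S))
    }
    I[i, j] <- tot
    I[j, i] <- tot
  }
  diag(I) <- shap_brute(forest, x, p) - rowSums(I)
  I
}

# --- small fixtures -------------------------------------------------------

# confounded cohort with deliberately unequal arms (a large treated pool vs
# a small comparison arm, like a naturalistic registry), so that 1:1
# matching actually selects controls and can improve balance
unequal_cohort <- function(seed, n_big = 200, n_small = 70) {
  sim <- simulate_cohort(sim_config(n_per_arm = n_big, seed = seed))
  co <- sim$cohort
  keep_ket <- head(co$patient_id[co$treatment == "KET"], n_small)
  co[co$treatment == "ECT" | co$patient_id %in% keep_ket, , drop = FALSE]
}

# tiny imputed cohort for learner-level tests (no missingness machinery)
tiny_cohort <- function(n_per_arm = 30, seed = 1, noise_sd = 1) {
  sim <- simulate_cohort(sim_config(
    n_per_arm = n_per_arm, seed = seed, p_binary = 3, noise_sd = noise_sd,
    moca_missing_rate_by_arm = c(ECT = 0, KET = 0), basis_missing_rate = 0
  ))
  sim
}

expect_no_na <- function(x) expect_false(anyNA(x))
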