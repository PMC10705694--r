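// Path-dependent tree-SHAP for regression forests, with conditional runs
// used to assemble SHAP interaction values (Lundberg's polynomial-time
// algorithm: maintain the set of unique features on the current path with
// their one/zero fractions and Shapley permutation weights).
//
// Trees arrive as parallel arrays (0-based children, -1 for "leaf"), with
// per-node covers computed from the bootstrap (in-bag) training sample, so
// the "feature missing" expectation splits proportionally to the data each
// branch actually saw during training.

#include <Rcpp.h>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *unique_path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; --i) {
    unique_path[i + 1].pweight +=
        one_fraction * unique_path[i].pweight * (i + 1.0) / (unique_depth + 1.0);
    unique_path[i].pweight =
        zero_fraction * unique_path[i].pweight * (unique_depth - i) / (unique_depth + 1.0);
  }
}

static void unwind_path(PathElement *unique_path, int unique_depth,
                        int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;

  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1.0)
                               / ((i + 1.0) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction
                               * (unique_depth - i) / (unique_depth + 1.0);
    } else {
      unique_path[i].pweight = (unique_path[i].pweight * (unique_depth + 1.0))
                               / (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *unique_path, int unique_depth,
                               int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1.0)
                         / ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight - tmp * zero_fraction
                         * ((unique_depth - i) / (unique_depth + 1.0));
    } else {
      total += (unique_path[i].pweight / zero_fraction)
               / ((unique_depth - i) / (unique_depth + 1.0));
    }
  }
  return total;
}

struct Tree {
  const int *left, *right, *feature;
  const double *threshold, *value, *cover;
};

static void tree_shap_recursive(const Tree &tr, const double *x, double *phi,
                                int node, int unique_depth,
                                PathElement *parent_unique_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index,
                                int condition, int condition_feature,
                                double condition_fraction) {
  if (condition_fraction == 0.0) return;

  PathElement *unique_path = parent_unique_path + unique_depth + 1;
  std::copy(parent_unique_path, parent_unique_path + unique_depth + 1,
            unique_path);
  if (condition == 0 || condition_feature != parent_feature_index) {
    extend_path(unique_path, unique_depth, parent_zero_fraction,
                parent_one_fraction, parent_feature_index);
  }
  const int split_index = tr.feature[node];

  if (tr.left[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction)
                               * tr.value[node] * condition_fraction;
    }
    return;
  }

  const int hot = (x[split_index] <= tr.threshold[node]) ? tr.left[node]
                                                         : tr.right[node];
  const int cold = (hot == tr.left[node]) ? tr.right[node] : tr.left[node];
  const double w = tr.cover[node];
  const double hot_zero_fraction = tr.cover[hot] / w;
  const double cold_zero_fraction = tr.cover[cold] / w;
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  // previously split on this feature? undo that entry and merge fractions
  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (unique_path[path_index].feature_index == split_index) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  double hot_condition_fraction = condition_fraction;
  double cold_condition_fraction = condition_fraction;
  if (condition > 0 && split_index == condition_feature) {
    cold_condition_fraction = 0;
    unique_depth -= 1;  // this feature is never added to the path
  } else if (condition < 0 && split_index == condition_feature) {
    hot_condition_fraction *= hot_zero_fraction;
    cold_condition_fraction *= cold_zero_fraction;
    unique_depth -= 1;
  }

  tree_shap_recursive(tr, x, phi, hot, unique_depth + 1, unique_path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_index, condition,
                      condition_feature, hot_condition_fraction);
  tree_shap_recursive(tr, x, phi, cold, unique_depth + 1, unique_path,
                      cold_zero_fraction * incoming_zero_fraction, 0.0,
                      split_index, condition, condition_feature,
                      cold_condition_fraction);
}

static int tree_max_depth(const IntegerVector &left, const IntegerVector &right) {
  const int n = left.size();
  std::vector<int> depth(n, 0);
  int maxd = 0;
  for (int i = 0; i < n; ++i) {  // parents precede children in ranger's layout
    if (left[i] >= 0) {
      depth[left[i]] = depth[i] + 1;
      depth[right[i]] = depth[i] + 1;
      maxd = std::max(maxd, depth[i] + 1);
    }
  }
  return maxd;
}

// Per-node cover: total bootstrap weight of training rows reaching each node.
// [[Rcpp::export]]
NumericVector cpp_node_cover(IntegerVector left, IntegerVector right,
                             IntegerVector feature, NumericVector threshold,
                             NumericMatrix X, NumericVector w) {
  NumericVector cover(left.size());
  for (int i = 0; i < X.nrow(); ++i) {
    const double wi = w[i];
    if (wi <= 0) continue;
    int node = 0;
    for (;;) {
      cover[node] += wi;
      if (left[node] < 0) break;
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
  }
  return cover;
}

// Forest prediction by explicit traversal (mean over trees); used to verify
// that the extracted tree structures reproduce the fitted model.
// [[Rcpp::export]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tl = trees[t];
    IntegerVector left = tl["left"], right = tl["right"], feature = tl["feature"];
    NumericVector threshold = tl["threshold"], value = tl["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (left[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      }
      out[i] += value[node];
    }
  }
  return out / (double)T;
}

// Cover-weighted expectation of each tree, averaged: the SHAP baseline.
// [[Rcpp::export]]
double cpp_forest_expected(List trees) {
  double total = 0;
  const int T = trees.size();
  for (int t = 0; t < T; ++t) {
    List tl = trees[t];
    IntegerVector left = tl["left"];
    NumericVector value = tl["value"], cover = tl["cover"];
    double e = 0;
    for (int i = 0; i < left.size(); ++i) {
      if (left[i] < 0) e += cover[i] * value[i];
    }
    total += e / cover[0];
  }
  return total / (double)T;
}

// SHAP values (condition == 0) or conditional SHAP runs (condition = +/-1 on
// condition_feature, 0-based) for every row of X. Returns n x p matrix of
// per-feature attributions averaged over trees.
// [[Rcpp::export]]
NumericMatrix cpp_forest_shap(List trees, NumericMatrix X, int n_features,
                              int condition = 0, int condition_feature = -1) {
  const int n = X.nrow(), T = trees.size();
  NumericMatrix phi(n, n_features);
  std::vector<double> xrow(X.ncol());
  std::vector<double> phirow(n_features);

  for (int t = 0; t < T; ++t) {
    List tl = trees[t];
    IntegerVector left = tl["left"], right = tl["right"], feature = tl["feature"];
    NumericVector threshold = tl["threshold"], value = tl["value"], cover = tl["cover"];
    Tree tr{INTEGER(left), INTEGER(right), INTEGER(feature),
            REAL(threshold), REAL(value), REAL(cover)};
    const int D = tree_max_depth(left, right) + 2;
    std::vector<PathElement> path((size_t)(D * (D + 1)) / 2 + D);

    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < X.ncol(); ++j) xrow[j] = X(i, j);
      std::fill(phirow.begin(), phirow.end(), 0.0);
      tree_shap_recursive(tr, xrow.data(), phirow.data(), 0, 0, path.data(),
                          1.0, 1.0, -1, condition, condition_feature, 1.0);
      for (int j = 0; j < n_features; ++j) phi(i, j) += phirow[j];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n_features; ++j) phi(i, j) /= (double)T;
  return phi;
}
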