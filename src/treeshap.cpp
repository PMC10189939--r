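#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact tree-path Shapley attributions for binary trees with "go left when
// x <= threshold" splits (the ranger convention). Conditioning is
// path-dependent: when a split feature is out of the coalition, its
// children are weighted by their training cover. Covers are computed here
// by routing the training matrix through each tree, since the fitted
// forest object does not expose per-node sample counts.

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(std::vector<PathElement> &path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[unique_depth].feature_index = feature_index;
  path[unique_depth].zero_fraction = zero_fraction;
  path[unique_depth].one_fraction = one_fraction;
  path[unique_depth].pweight = (unique_depth == 0) ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1.0) / (unique_depth + 1.0);
    path[i].pweight = zero_fraction * path[i].pweight * (unique_depth - i) / (unique_depth + 1.0);
  }
}

static void unwind_path(std::vector<PathElement> &path, int unique_depth,
                        int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0.0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (unique_depth + 1.0) / ((i + 1.0) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction * (unique_depth - i) / (unique_depth + 1.0);
    } else {
      path[i].pweight = (path[i].pweight * (unique_depth + 1.0)) /
                        (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const std::vector<PathElement> &path,
                               int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0.0) {
      const double tmp = next_one_portion * (unique_depth + 1.0) / ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight - tmp * zero_fraction * (unique_depth - i) / (unique_depth + 1.0);
    } else {
      total += (path[i].pweight / zero_fraction) / ((unique_depth - i) / (unique_depth + 1.0));
    }
  }
  return total;
}

struct Tree {
  const int *left;
  const int *right;
  const int *feature;
  const double *threshold;
  const double *value;
  std::vector<double> cover;
};

static void tree_shap_recurse(const Tree &tree, const NumericMatrix &X, int row,
                              double *phi, int node,
                              std::vector<PathElement> path, int unique_depth,
                              double parent_zero_fraction,
                              double parent_one_fraction,
                              int parent_feature_index) {
  path.resize(unique_depth + 2);
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);

  if (tree.feature[node] < 0) { // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      const PathElement &el = path[i];
      phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction) * tree.value[node];
    }
    return;
  }

  const int split = tree.feature[node];
  const int l = tree.left[node];
  const int r = tree.right[node];
  int hot, cold;
  if (X(row, split) <= tree.threshold[node]) { hot = l; cold = r; }
  else { hot = r; cold = l; }
  const double denom = tree.cover[node];
  double hot_zero = (denom > 0) ? tree.cover[hot] / denom : 0.5;
  double cold_zero = (denom > 0) ? tree.cover[cold] / denom : 0.5;
  double incoming_zero = 1.0, incoming_one = 1.0;

  // same feature already on the path: undo and fold in
  int k = 0;
  for (int i = 1; i <= unique_depth; ++i) {
    if (path[i].feature_index == split) { k = i; break; }
  }
  if (k > 0) {
    incoming_zero = path[k].zero_fraction;
    incoming_one = path[k].one_fraction;
    unwind_path(path, unique_depth, k);
    unique_depth -= 1;
  }

  tree_shap_recurse(tree, X, row, phi, hot, path, unique_depth + 1,
                    hot_zero * incoming_zero, incoming_one, split);
  tree_shap_recurse(tree, X, row, phi, cold, path, unique_depth + 1,
                    cold_zero * incoming_zero, 0.0, split);
}

static void compute_cover(Tree &tree, int n_nodes, const NumericMatrix &Xtrain) {
  tree.cover.assign(n_nodes, 0.0);
  const int n = Xtrain.nrow();
  for (int s = 0; s < n; ++s) {
    int node = 0;
    for (;;) {
      tree.cover[node] += 1.0;
      const int f = tree.feature[node];
      if (f < 0) break;
      node = (Xtrain(s, f) <= tree.threshold[node]) ? tree.left[node] : tree.right[node];
    }
  }
}

static double tree_expected_value(const Tree &tree, int node) {
  if (tree.feature[node] < 0) return tree.value[node];
  const double denom = tree.cover[node];
  const double wl = (denom > 0) ? tree.cover[tree.left[node]] / denom : 0.5;
  const double wr = (denom > 0) ? tree.cover[tree.right[node]] / denom : 0.5;
  return wl * tree_expected_value(tree, tree.left[node]) +
         wr * tree_expected_value(tree, tree.right[node]);
}

// [[Rcpp::export]]
List treeshap_cpp(NumericMatrix X, NumericMatrix Xtrain, List forest) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int ntree = forest.size();
  NumericMatrix phi(n, p);
  double base = 0.0;

  for (int t = 0; t < ntree; ++t) {
    List tr = forest[t];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    NumericVector value = tr["value"];
    Tree tree;
    tree.left = left.begin();
    tree.right = right.begin();
    tree.feature = feature.begin();
    tree.threshold = threshold.begin();
    tree.value = value.begin();
    compute_cover(tree, left.size(), Xtrain);
    base += tree_expected_value(tree, 0);

    std::vector<double> phirow(p);
    std::vector<PathElement> path;
    for (int s = 0; s < n; ++s) {
      std::fill(phirow.begin(), phirow.end(), 0.0);
      tree_shap_recurse(tree, X, s, phirow.data(), 0, path, 0, 1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) {
        if (phirow[j] != 0.0) phi(s, j) += phirow[j];
      }
    }
    Rcpp::checkUserInterrupt();
  }
  const double scale = 1.0 / ntree;
  for (int s = 0; s < n; ++s)
    for (int j = 0; j < p; ++j) phi(s, j) *= scale;
  return List::create(_["phi"] = phi, _["base"] = base * scale);
}
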