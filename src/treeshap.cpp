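// Exact path-dependent TreeSHAP for regression tree ensembles.
//
// Implements the polynomial-time Shapley value algorithm for a single
// decision tree, conditioning by tree-path cover proportions. Node arrays
// come from randomForest::getTree(): 0-based child indices with -1 marking
// "no child" (leaves), 0-based split features, and "go left iff
// x[feature] <= split". Covers are the (in-bag-weighted) number of
// training rows reaching each node, so every internal node has positive
// cover on both children.
//
// The additivity identity  base + sum_j phi_j = tree prediction  holds
// exactly (up to floating point) for every sample, which the test suite
// asserts, alongside agreement with a brute-force subset-enumeration
// Shapley oracle on small trees.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *path, unsigned depth,
                        double zero_fraction, double one_fraction, int fi) {
  path[depth].feature_index = fi;
  path[depth].zero_fraction = zero_fraction;
  path[depth].one_fraction = one_fraction;
  path[depth].pweight = (depth == 0 ? 1.0 : 0.0);
  for (int i = static_cast<int>(depth) - 1; i >= 0; i--) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1.0)
                           / (depth + 1.0);
    path[i].pweight = zero_fraction * path[i].pweight * (depth - i)
                      / (depth + 1.0);
  }
}

static void unwind_path(PathElement *path, unsigned depth, unsigned index) {
  const double one = path[index].one_fraction;
  const double zero = path[index].zero_fraction;
  double next_one = path[depth].pweight;
  for (int i = static_cast<int>(depth) - 1; i >= 0; --i) {
    if (one != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one * (depth + 1.0) / ((i + 1.0) * one);
      next_one = tmp - path[i].pweight * zero * (depth - i) / (depth + 1.0);
    } else {
      path[i].pweight = (path[i].pweight * (depth + 1.0))
                        / (zero * (depth - i));
    }
  }
  for (unsigned i = index; i < depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *path, unsigned depth,
                               unsigned index) {
  const double one = path[index].one_fraction;
  const double zero = path[index].zero_fraction;
  double next_one = path[depth].pweight;
  double total = 0;
  for (int i = static_cast<int>(depth) - 1; i >= 0; --i) {
    if (one != 0) {
      const double tmp = next_one * (depth + 1.0) / ((i + 1.0) * one);
      total += tmp;
      next_one = path[i].pweight - tmp * zero * (depth - i) / (depth + 1.0);
    } else {
      total += (path[i].pweight / zero) * (depth + 1.0) / (depth - i);
    }
  }
  return total;
}

struct Tree {
  const int *ld, *rd, *var;
  const double *split, *value, *cover;
};

static void tree_shap_recursive(const Tree &t, const double *x, double *phi,
                                int node, unsigned unique_depth,
                                PathElement *parent_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  PathElement *path = parent_path + unique_depth + 1;
  std::copy(parent_path, parent_path + unique_depth + 1, path);
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);

  if (t.ld[node] < 0) {  // leaf
    for (unsigned i = 1; i <= unique_depth; ++i) {
      const PathElement &el = path[i];
      // a branch with neither training cover nor the sample contributes
      // exactly zero; skipping avoids a 0/0 in the unwind
      if (el.one_fraction == 0 && el.zero_fraction == 0) continue;
      const double w = unwound_path_sum(path, unique_depth, i);
      phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction)
                               * t.value[node];
    }
    return;
  }

  const int f = t.var[node];
  const int hot = (x[f] <= t.split[node]) ? t.ld[node] : t.rd[node];
  const int cold = (hot == t.ld[node]) ? t.rd[node] : t.ld[node];
  // a node can end up with zero cover when the reported split point
  // routes every weighted training row to one side; its subtree then
  // carries no conditional mass
  const double w = t.cover[node];
  const double hot_zero_fraction = (w > 0) ? t.cover[hot] / w : 0.0;
  const double cold_zero_fraction = (w > 0) ? t.cover[cold] / w : 0.0;
  double incoming_zero_fraction = 1.0, incoming_one_fraction = 1.0;

  unsigned k = 0;
  for (; k <= unique_depth; ++k)
    if (path[k].feature_index == f) break;
  if (k != unique_depth + 1) {
    incoming_zero_fraction = path[k].zero_fraction;
    incoming_one_fraction = path[k].one_fraction;
    unwind_path(path, unique_depth, k);
    unique_depth -= 1;
  }

  tree_shap_recursive(t, x, phi, hot, unique_depth + 1, path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, f);
  tree_shap_recursive(t, x, phi, cold, unique_depth + 1, path,
                      cold_zero_fraction * incoming_zero_fraction, 0.0, f);
}

static int tree_max_depth(const int *ld, const int *rd, int node) {
  if (ld[node] < 0) return 1;
  return 1 + std::max(tree_max_depth(ld, rd, ld[node]),
                      tree_max_depth(ld, rd, rd[node]));
}

// Cover (sum of row weights reaching each node) for one tree.
// [[Rcpp::export]]
NumericVector cpp_node_cover(IntegerVector ld, IntegerVector rd,
                             IntegerVector var, NumericVector split,
                             NumericMatrix X, NumericVector w) {
  const int n = X.nrow();
  NumericVector cover(ld.size());
  for (int i = 0; i < n; ++i) {
    const double wi = w[i];
    if (wi == 0) continue;
    int node = 0;
    for (;;) {
      cover[node] += wi;
      if (ld[node] < 0) break;
      node = (X(i, var[node]) <= split[node]) ? ld[node] : rd[node];
    }
  }
  return cover;
}

// SHAP values of one tree for every row of X; returns list(phi, base).
// [[Rcpp::export]]
List cpp_tree_shap(IntegerVector ld, IntegerVector rd, IntegerVector var,
                   NumericVector split, NumericVector value,
                   NumericVector cover, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  const Tree t = {ld.begin(), rd.begin(), var.begin(), split.begin(),
                  value.begin(), cover.begin()};

  double base = 0;
  for (int j = 0; j < ld.size(); ++j)
    if (ld[j] < 0) base += value[j] * cover[j];
  base /= cover[0];

  const int maxd = tree_max_depth(ld.begin(), rd.begin(), 0) + 2;
  std::vector<PathElement> buf((maxd * (maxd + 1)) / 2);
  std::vector<double> xrow(p), phirow(p);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) { xrow[j] = X(i, j); phirow[j] = 0.0; }
    tree_shap_recursive(t, xrow.data(), phirow.data(), 0, 0, buf.data(),
                        1.0, 1.0, -1);
    for (int j = 0; j < p; ++j) phi(i, j) = phirow[j];
  }
  return List::create(Named("phi") = phi, Named("base") = base);
}

// Routed prediction of one tree for every row of X (used for checking the
// routing convention against randomForest's own predictions).
// [[Rcpp::export]]
NumericVector cpp_tree_predict(IntegerVector ld, IntegerVector rd,
                               IntegerVector var, NumericVector split,
                               NumericVector value, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (ld[node] >= 0)
      node = (X(i, var[node]) <= split[node]) ? ld[node] : rd[node];
    out[i] = value[node];
  }
  return out;
}
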