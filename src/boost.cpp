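// Stochastic gradient boosting of least-squares regression trees for a
// binomial (logit) response. Trees are grown depth-first with a depth limit
// (tree complexity tc) by exhaustive greedy split search; terminal nodes
// carry one-step Newton estimates. Deterministic under a caller seed.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeBuf {
  // parallel node arrays; var = -1 marks a terminal node
  std::vector<int> var;
  std::vector<double> split;
  std::vector<int> left, right;
  std::vector<double> value;   // Newton leaf estimate (unscaled by lr)
  std::vector<double> improve; // squared-error reduction at the split

  int add_node() {
    var.push_back(-1);
    split.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    improve.push_back(0.0);
    return (int)var.size() - 1;
  }
};

const double GAMMA_CAP = 10.0;

double leaf_value(const std::vector<int> &idx, const std::vector<double> &r,
                  const std::vector<double> &h) {
  double sr = 0.0, sh = 0.0;
  for (int i : idx) {
    sr += r[i];
    sh += h[i];
  }
  if (sh < 1e-10) sh = 1e-10;
  double g = sr / sh;
  if (g > GAMMA_CAP) g = GAMMA_CAP;
  if (g < -GAMMA_CAP) g = -GAMMA_CAP;
  return g;
}

// Greedy split of the rows in idx. Returns false when no admissible split
// improves on the parent. Ties broken by lowest predictor index, then lowest
// threshold (strict > on improvement keeps the first candidate found).
bool best_split(const NumericMatrix &X, const std::vector<double> &r,
                const std::vector<int> &idx, int min_obs, int &out_var,
                double &out_split, double &out_improve) {
  const int n = (int)idx.size();
  if (n < 2 * min_obs) return false;
  double S = 0.0;
  for (int i : idx) S += r[i];
  const double parent = S * S / n;

  out_var = -1;
  out_improve = 0.0;
  std::vector<std::pair<double, double>> xv(n); // (x, residual)
  for (int j = 0; j < X.ncol(); ++j) {
    for (int k = 0; k < n; ++k) xv[k] = {X(idx[k], j), r[idx[k]]};
    std::sort(xv.begin(), xv.end(),
              [](const std::pair<double, double> &a,
                 const std::pair<double, double> &b) { return a.first < b.first; });
    double SL = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      SL += xv[k].second;
      if (xv[k].first == xv[k + 1].first) continue; // not a boundary
      int nL = k + 1, nR = n - nL;
      if (nL < min_obs || nR < min_obs) continue;
      double SR = S - SL;
      double imp = SL * SL / nL + SR * SR / nR - parent;
      if (imp > out_improve + 1e-12) {
        out_improve = imp;
        out_var = j;
        out_split = 0.5 * (xv[k].first + xv[k + 1].first);
      }
    }
  }
  return out_var >= 0;
}

void grow(TreeBuf &tree, int node, const NumericMatrix &X,
          const std::vector<double> &r, const std::vector<double> &h,
          std::vector<int> &idx, int depth, int max_depth, int min_obs) {
  int v;
  double s, imp;
  if (depth >= max_depth || !best_split(X, r, idx, min_obs, v, s, imp)) {
    tree.value[node] = leaf_value(idx, r, h);
    return;
  }
  std::vector<int> li, ri;
  li.reserve(idx.size());
  ri.reserve(idx.size());
  for (int i : idx)
    (X(i, v) <= s ? li : ri).push_back(i);
  tree.var[node] = v;
  tree.split[node] = s;
  tree.improve[node] = imp;
  int L = tree.add_node(), R = tree.add_node();
  tree.left[node] = L;
  tree.right[node] = R;
  std::vector<int>().swap(idx); // free parent index memory before recursing
  grow(tree, L, X, r, h, li, depth + 1, max_depth, min_obs);
  std::vector<int>().swap(li);
  grow(tree, R, X, r, h, ri, depth + 1, max_depth, min_obs);
}

NumericMatrix pack(const TreeBuf &t) {
  int n = (int)t.var.size();
  NumericMatrix m(n, 6);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = t.var[i];
    m(i, 1) = t.split[i];
    m(i, 2) = t.left[i];
    m(i, 3) = t.right[i];
    m(i, 4) = t.value[i];
    m(i, 5) = t.improve[i];
  }
  colnames(m) = CharacterVector::create("var", "split", "left", "right",
                                        "value", "improve");
  return m;
}

} // namespace

// Adds n_trees boosting stages to the linear-predictor state F (logit scale).
// Returns the new trees and the updated F; the caller owns the intercept and
// the concatenation of stages across calls.
// [[Rcpp::export]]
List cpp_boost(NumericMatrix X, NumericVector y, NumericVector F_in,
               int n_trees, int tc, double lr, double bf, int min_obs,
               int seed) {
  const int n = X.nrow();
  std::vector<double> F(F_in.begin(), F_in.end());
  std::vector<double> r(n), h(n), p(n);
  std::mt19937 rng((unsigned)seed);
  List trees(n_trees);

  std::vector<int> all(n), bag;
  for (int i = 0; i < n; ++i) all[i] = i;
  int m = (int)std::lround(bf * n);
  if (m < 1) m = 1;
  if (m > n) m = n;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      p[i] = 1.0 / (1.0 + std::exp(-F[i]));
      r[i] = y[i] - p[i];
      h[i] = p[i] * (1.0 - p[i]);
    }
    // bag: partial Fisher-Yates draw of m indices without replacement
    bag.assign(all.begin(), all.end());
    if (m < n) {
      for (int k = 0; k < m; ++k) {
        std::uniform_int_distribution<int> U(k, n - 1);
        std::swap(bag[k], bag[U(rng)]);
      }
      bag.resize(m);
      std::sort(bag.begin(), bag.end());
    }
    TreeBuf tb;
    tb.add_node();
    std::vector<int> idx(bag);
    grow(tb, 0, X, r, h, idx, 0, tc, min_obs);
    NumericMatrix packed = pack(tb);
    trees[t] = packed;
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while ((int)packed(k, 0) >= 0)
        k = (X(i, (int)packed(k, 0)) <= packed(k, 1)) ? (int)packed(k, 2)
                                                      : (int)packed(k, 3);
      F[i] += lr * packed(k, 4);
    }
  }
  return List::create(_["trees"] = trees,
                      _["F"] = NumericVector(F.begin(), F.end()));
}

// Sum of (unshrunken) leaf values of the first n_use trees for each row.
// [[Rcpp::export]]
NumericVector cpp_tree_sum(List trees, NumericMatrix X, int n_use) {
  const int n = X.nrow();
  NumericVector out(n, 0.0);
  int T = std::min<int>(n_use, trees.size());
  for (int t = 0; t < T; ++t) {
    NumericMatrix tr = trees[t];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while ((int)tr(k, 0) >= 0)
        k = (X(i, (int)tr(k, 0)) <= tr(k, 1)) ? (int)tr(k, 2) : (int)tr(k, 3);
      out[i] += tr(k, 4);
    }
  }
  return out;
}
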