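#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Extra-Trees regression importance for one target.
//
// Grows totally randomized trees: at each node, k_features candidate
// predictors are drawn without replacement, each gets a uniform random
// cut point between its min and max over the node's samples, and the
// split with the largest variance reduction wins. Importance of a
// predictor is the sum over its split nodes of
//   n_node * var(node) - n_left * var(left) - n_right * var(right),
// accumulated over all trees and normalized to sum to one per target.

namespace {

struct NodeTask {
  std::vector<int> idx;  // sample indices in this node
};

double node_var_sum(const std::vector<int>& idx, const double* y) {
  // returns n * variance (sum of squared deviations)
  double s = 0.0, s2 = 0.0;
  for (int i : idx) { s += y[i]; s2 += y[i] * y[i]; }
  double n = static_cast<double>(idx.size());
  return s2 - s * s / n;
}

void grow_tree(const NumericMatrix& Xp, const double* y,
               std::vector<double>& imp, int k_features, int min_leaf,
               std::mt19937& rng) {
  int p = Xp.ncol();
  int n = Xp.nrow();
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  std::vector<NodeTask> stack;
  stack.push_back({all});
  std::vector<int> feat(p);
  for (int j = 0; j < p; ++j) feat[j] = j;

  while (!stack.empty()) {
    NodeTask node = std::move(stack.back());
    stack.pop_back();
    int nn = static_cast<int>(node.idx.size());
    if (nn < 2 * min_leaf) continue;
    double ss_node = node_var_sum(node.idx, y);
    if (ss_node <= 1e-12) continue;

    // draw k candidate features without replacement
    int k = std::min(k_features, p);
    for (int j = 0; j < k; ++j) {
      std::uniform_int_distribution<int> pickj(j, p - 1);
      std::swap(feat[j], feat[pickj(rng)]);
    }

    int best_f = -1;
    double best_cut = 0.0, best_gain = 0.0;
    for (int j = 0; j < k; ++j) {
      int f = feat[j];
      double lo = R_PosInf, hi = R_NegInf;
      for (int i : node.idx) {
        double v = Xp(i, f);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (hi <= lo) continue;
      std::uniform_real_distribution<double> cutd(lo, hi);
      double cut = cutd(rng);
      double sl = 0, sl2 = 0, sr = 0, sr2 = 0;
      int nl = 0;
      for (int i : node.idx) {
        double v = Xp(i, f);
        if (v <= cut) { sl += y[i]; sl2 += y[i] * y[i]; ++nl; }
        else { sr += y[i]; sr2 += y[i] * y[i]; }
      }
      int nr = nn - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double ssl = sl2 - sl * sl / nl;
      double ssr = sr2 - sr * sr / nr;
      double gain = ss_node - ssl - ssr;
      if (gain > best_gain) { best_gain = gain; best_f = f; best_cut = cut; }
    }
    if (best_f < 0) continue;
    imp[best_f] += best_gain;
    NodeTask left, right;
    for (int i : node.idx) {
      if (Xp(i, best_f) <= best_cut) left.idx.push_back(i);
      else right.idx.push_back(i);
    }
    stack.push_back(std::move(left));
    stack.push_back(std::move(right));
  }
}

}  // namespace

// [[Rcpp::export(name = ".extratrees_importance")]]
NumericVector extratrees_importance(NumericMatrix Xp, NumericVector y,
                                    int n_trees, int k_features,
                                    int min_leaf, int seed) {
  int p = Xp.ncol();
  std::vector<double> imp(p, 0.0);
  std::mt19937 rng(static_cast<std::uint32_t>(seed));
  for (int t = 0; t < n_trees; ++t)
    grow_tree(Xp, REAL(y), imp, k_features, min_leaf, rng);
  double tot = 0.0;
  for (double v : imp) tot += v;
  NumericVector out(p);
  for (int j = 0; j < p; ++j) out[j] = tot > 0 ? imp[j] / tot : 0.0;
  return out;
}
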