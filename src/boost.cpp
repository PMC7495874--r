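// Gradient-boosted decision trees for binary classification.
//
// Second-order boosting on the logistic loss: each tree is fit to the
// per-sample gradients g = p - y and hessians h = p (1 - p) of the
// current raw score, splits are found by exact greedy search maximising
//   gain = 1/2 [ GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda) ]
// and leaf weights are the Newton step -G/(H+lambda), shrunk by the
// learning rate. lambda = 1 and min child hessian = 1 (the usual
// defaults). No row or column subsampling, so fitting is fully
// deterministic: identical data always yield identical ensembles.
//
// Trees are returned flattened: one row per node with columns
// (feature, threshold, left, right, value); feature = -1 marks a leaf.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x < threshold
  int left, right;  // child node ids, -1 for leaf
  double value;     // leaf weight (already shrunk)
};

struct Builder {
  const NumericMatrix& X;
  const std::vector<double>& g;
  const std::vector<double>& h;
  double lambda, eta, min_child_weight;
  int max_depth;
  std::vector<Node> nodes;

  Builder(const NumericMatrix& X_, const std::vector<double>& g_,
          const std::vector<double>& h_, double lambda_, double eta_,
          double mcw_, int max_depth_)
      : X(X_), g(g_), h(h_), lambda(lambda_), eta(eta_),
        min_child_weight(mcw_), max_depth(max_depth_) {}

  int leaf(double G, double H) {
    Node nd;
    nd.feature = -1;
    nd.threshold = 0.0;
    nd.left = nd.right = -1;
    nd.value = -eta * G / (H + lambda);
    nodes.push_back(nd);
    return (int)nodes.size() - 1;
  }

  int build(std::vector<int>& idx, int depth) {
    double G = 0.0, H = 0.0;
    for (int i : idx) { G += g[i]; H += h[i]; }
    if (depth >= max_depth || idx.size() < 2) return leaf(G, H);

    double parent_score = G * G / (H + lambda);
    double best_gain = 0.0;
    int best_feat = -1;
    double best_thr = 0.0;
    int p = X.ncol();
    std::vector<int> ord(idx);
    for (int f = 0; f < p; ++f) {
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double xa = X(a, f), xb = X(b, f);
        if (xa != xb) return xa < xb;
        return a < b; // deterministic
      });
      double GL = 0.0, HL = 0.0;
      for (size_t r = 0; r + 1 < ord.size(); ++r) {
        GL += g[ord[r]];
        HL += h[ord[r]];
        double xr = X(ord[r], f), xn = X(ord[r + 1], f);
        if (xr == xn) continue; // can't split between equal values
        double HR = H - HL, GR = G - GL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        double gain = 0.5 * (GL * GL / (HL + lambda) +
                             GR * GR / (HR + lambda) - parent_score);
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (xr + xn);
        }
      }
    }
    if (best_feat < 0) return leaf(G, H);

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_feat) < best_thr) li.push_back(i); else ri.push_back(i);
    }
    Node nd;
    nd.feature = best_feat;
    nd.threshold = best_thr;
    nd.value = 0.0;
    int me = (int)nodes.size();
    nodes.push_back(nd);
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

double tree_predict(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) < tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

} // namespace

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, int n_trees,
                 double learning_rate, int max_depth, double lambda,
                 double min_child_weight, double base_score) {
  int n = X.nrow();
  double base_raw = std::log(base_score / (1.0 - base_score));
  std::vector<double> raw(n, base_raw), g(n), h(n);
  List trees(n_trees);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-raw[i]));
      g[i] = p - y[i];
      h[i] = p * (1.0 - p);
    }
    Builder b(X, g, h, lambda, learning_rate, min_child_weight, max_depth);
    std::vector<int> idx(all);
    b.build(idx, 0);
    int m = (int)b.nodes.size();
    NumericMatrix tm(m, 5);
    for (int k = 0; k < m; ++k) {
      tm(k, 0) = b.nodes[k].feature;
      tm(k, 1) = b.nodes[k].threshold;
      tm(k, 2) = b.nodes[k].left;
      tm(k, 3) = b.nodes[k].right;
      tm(k, 4) = b.nodes[k].value;
    }
    trees[t] = tm;
    for (int i = 0; i < n; ++i) raw[i] += tree_predict(tm, X, i);
  }
  return List::create(_["trees"] = trees, _["base_raw"] = base_raw);
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List trees, double base_raw, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n);
  std::vector<double> raw(n, base_raw);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) raw[i] += tree_predict(tm, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-raw[i]));
  return out;
}
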