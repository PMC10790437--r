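#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Extremely-randomized regression trees used by the iterative
// tree-ensemble imputer.  Self-contained xorshift RNG keeps results
// identical across platforms and independent of R's RNG stream.

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(unif() * n) % n; }
};

struct Node {
  int feat;      // -1 for leaf
  double thr;
  int left, right;
  double value;
};

struct Tree {
  std::vector<Node> nodes;
};

struct Builder {
  const NumericMatrix& X;
  const std::vector<double>& y;
  int mtry, min_node, max_depth;
  XorShift& rng;
  Tree& tree;

  Builder(const NumericMatrix& X_, const std::vector<double>& y_,
          int mtry_, int min_node_, int max_depth_, XorShift& rng_, Tree& t_)
    : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_),
      rng(rng_), tree(t_) {}

  int build(std::vector<int>& idx, int depth) {
    const int n = (int) idx.size();
    double sum = 0.0, sum2 = 0.0;
    for (int i : idx) { sum += y[i]; sum2 += y[i] * y[i]; }
    double mean = sum / n;
    double sse = sum2 - sum * mean;

    Node nd; nd.feat = -1; nd.thr = 0.0; nd.left = -1; nd.right = -1;
    nd.value = mean;
    int id = (int) tree.nodes.size();
    tree.nodes.push_back(nd);
    if (n < 2 * min_node || depth >= max_depth || sse <= 1e-12) return id;

    // mtry candidates: random feature + random threshold within its range
    int best_feat = -1; double best_thr = 0.0, best_gain = 0.0;
    const int p = X.ncol();
    for (int c = 0; c < mtry; ++c) {
      int f = rng.below(p);
      double lo = R_PosInf, hi = R_NegInf;
      for (int i : idx) {
        double v = X(i, f);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (!(hi > lo)) continue;
      double thr = lo + rng.unif() * (hi - lo);
      double sL = 0.0, s2L = 0.0; int nL = 0;
      for (int i : idx)
        if (X(i, f) <= thr) { sL += y[i]; s2L += y[i] * y[i]; ++nL; }
      int nR = n - nL;
      if (nL < min_node || nR < min_node) continue;
      double sR = sum - sL, s2R = sum2 - s2L;
      double sseL = s2L - sL * sL / nL, sseR = s2R - sR * sR / nR;
      double gain = sse - (sseL + sseR);
      if (gain > best_gain) { best_gain = gain; best_feat = f; best_thr = thr; }
    }
    if (best_feat < 0) return id;

    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i : idx)
      (X(i, best_feat) <= best_thr ? li : ri).push_back(i);
    tree.nodes[id].feat = best_feat;
    tree.nodes[id].thr = best_thr;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    tree.nodes[id].left = l;
    tree.nodes[id].right = r;
    return id;
  }
};

double predict_one(const Tree& t, const NumericMatrix& X, int row) {
  int id = 0;
  while (t.nodes[id].feat >= 0)
    id = (X(row, t.nodes[id].feat) <= t.nodes[id].thr)
           ? t.nodes[id].left : t.nodes[id].right;
  return t.nodes[id].value;
}

} // namespace

// Fit an ensemble of randomized regression trees on (Xtr, ytr), each on a
// bootstrap resample, and return mean predictions for the rows of Xte.
// [[Rcpp::export(name = ".ert_regress")]]
NumericVector ert_regress(const NumericMatrix& Xtr, NumericVector ytr,
                          const NumericMatrix& Xte,
                          int ntree = 25, int mtry = 0,
                          int min_node = 5, int max_depth = 8,
                          int seed = 1) {
  const int n = Xtr.nrow(), m = Xte.nrow(), p = Xtr.ncol();
  if (mtry <= 0) mtry = std::max(1, (int) std::floor(std::sqrt((double) p)));
  std::vector<double> y(ytr.begin(), ytr.end());
  XorShift rng((uint64_t) seed * 2654435761ULL + 1ULL);
  NumericVector out(m);

  for (int b = 0; b < ntree; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n);
    Tree t;
    Builder bl(Xtr, y, mtry, min_node, max_depth, rng, t);
    bl.build(idx, 0);
    for (int j = 0; j < m; ++j) out[j] += predict_one(t, Xte, j);
  }
  for (int j = 0; j < m; ++j) out[j] /= ntree;
  return out;
}
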