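// Exact interventional Shapley attributions for a forest of regression
// trees, with the expectation taken over an explicit background sample.
//
// For one background row b, the coalition game is
//   v_b(F) = tree(composite(x on F, b elsewhere)).
// Each leaf of a tree is an axis-aligned box; feature f on the leaf's path
// is "x-consistent" if x[f] falls in the box slab and "b-consistent" if
// b[f] does. The leaf is reached by the composite iff every coalition
// feature is x-consistent and every out-of-coalition feature is
// b-consistent, so the leaf's indicator game depends only on
//   U = {f : x-consistent, not b-consistent}  (must be in F)
//   V = {f : b-consistent, not x-consistent}  (must be out of F),
// features consistent for both being null players and leaves with a
// feature consistent for neither being unreachable. The Shapley value of
// that indicator game is closed-form:
//   phi_f = +(u-1)! v! / (u+v)!   for f in U
//   phi_f = -u! (v-1)! / (u+v)!   for f in V
// with u = |U|, v = |V|. Summing leaf value x weight over leaves,
// background rows and trees gives the exact interventional attribution,
// identical to full subset enumeration but polynomial in tree size.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Leaf {
  double value;
  std::vector<int> feat;      // constrained feature indices (0-based)
  std::vector<double> lo, hi; // open/closed slab (lo, hi] per feature
};

void collect_leaves(const NumericMatrix& tree, int node, int p,
                    std::vector<double>& lo, std::vector<double>& hi,
                    std::vector<Leaf>& out) {
  // getTree columns: 0 left, 1 right, 2 split var (1-based), 3 split point,
  // 4 status (-1 terminal), 5 prediction
  if (tree(node, 4) == -1) {
    Leaf lf;
    lf.value = tree(node, 5);
    for (int f = 0; f < p; ++f) {
      if (lo[f] > -INFINITY || hi[f] < INFINITY) {
        lf.feat.push_back(f);
        lf.lo.push_back(lo[f]);
        lf.hi.push_back(hi[f]);
      }
    }
    out.push_back(lf);
    return;
  }
  int f = static_cast<int>(tree(node, 2)) - 1;
  double sp = tree(node, 3);
  int left = static_cast<int>(tree(node, 0)) - 1;
  int right = static_cast<int>(tree(node, 1)) - 1;
  double keep_hi = hi[f], keep_lo = lo[f];
  // left branch: x <= sp
  if (sp < hi[f]) hi[f] = sp;
  collect_leaves(tree, left, p, lo, hi, out);
  hi[f] = keep_hi;
  // right branch: x > sp
  if (sp > lo[f]) lo[f] = sp;
  collect_leaves(tree, right, p, lo, hi, out);
  lo[f] = keep_lo;
}

inline bool in_slab(double v, double lo, double hi) {
  return v > lo && v <= hi;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix forest_interventional_shap(List trees, NumericMatrix X,
                                         NumericMatrix B) {
  const int n = X.nrow(), p = X.ncol(), m = B.nrow(), ntree = trees.size();
  if (B.ncol() != p) stop("background and instances differ in feature count");
  NumericMatrix phi(n, p);

  // factorial ratios: fact[k] = k! as double (path feature counts are small)
  std::vector<double> fact(2 * p + 2, 1.0);
  for (size_t k = 1; k < fact.size(); ++k) fact[k] = fact[k - 1] * k;

  std::vector<double> lo(p), hi(p);
  std::vector<uint8_t> cx, cb;
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = trees[t];
    std::vector<Leaf> leaves;
    std::fill(lo.begin(), lo.end(), -INFINITY);
    std::fill(hi.begin(), hi.end(), INFINITY);
    collect_leaves(tree, 0, p, lo, hi, leaves);

    for (const Leaf& lf : leaves) {
      const int nc = static_cast<int>(lf.feat.size());
      if (nc == 0) continue; // root-only tree: constant, zero attribution
      cx.assign(static_cast<size_t>(n) * nc, 0);
      cb.assign(static_cast<size_t>(m) * nc, 0);
      for (int c = 0; c < nc; ++c) {
        const int f = lf.feat[c];
        for (int i = 0; i < n; ++i)
          cx[static_cast<size_t>(i) * nc + c] = in_slab(X(i, f), lf.lo[c], lf.hi[c]);
        for (int b = 0; b < m; ++b)
          cb[static_cast<size_t>(b) * nc + c] = in_slab(B(b, f), lf.lo[c], lf.hi[c]);
      }
      for (int i = 0; i < n; ++i) {
        const uint8_t* cxi = &cx[static_cast<size_t>(i) * nc];
        for (int b = 0; b < m; ++b) {
          const uint8_t* cbb = &cb[static_cast<size_t>(b) * nc];
          int u = 0, v = 0;
          bool dead = false;
          for (int c = 0; c < nc; ++c) {
            if (cxi[c]) {
              if (!cbb[c]) ++u;
            } else if (cbb[c]) {
              ++v;
            } else {
              dead = true;
              break;
            }
          }
          if (dead || (u == 0 && v == 0)) continue;
          const double denom = fact[u + v];
          const double w_pos = (u > 0) ? lf.value * fact[u - 1] * fact[v] / denom : 0.0;
          const double w_neg = (v > 0) ? lf.value * fact[u] * fact[v - 1] / denom : 0.0;
          for (int c = 0; c < nc; ++c) {
            if (cxi[c]) {
              if (!cbb[c]) phi(i, lf.feat[c]) += w_pos;
            } else {
              phi(i, lf.feat[c]) -= w_neg;
            }
          }
        }
      }
    }
  }
  const double scale = 1.0 / (static_cast<double>(ntree) * m);
  for (int i = 0; i < n; ++i)
    for (int f = 0; f < p; ++f) phi(i, f) *= scale;
  return phi;
}
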