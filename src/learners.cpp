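// Compact in-package learners used by the model-development pipeline.
// All randomness draws from R's RNG so set.seed() governs every fit.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------- Lomb
// Classic Lomb-Scargle power; equals half the RSS reduction of a
// least-squares sinusoid fit at each frequency.
// [[Rcpp::export]]
NumericVector lomb_power(NumericVector t, NumericVector y,
                         NumericVector freqs) {
  const int n = t.size(), nf = freqs.size();
  NumericVector out(nf);
  for (int k = 0; k < nf; ++k) {
    double w = 2.0 * M_PI * freqs[k];
    double s2 = 0.0, c2 = 0.0;
    for (int i = 0; i < n; ++i) {
      s2 += std::sin(2.0 * w * t[i]);
      c2 += std::cos(2.0 * w * t[i]);
    }
    double tau = std::atan2(s2, c2) / (2.0 * w);
    double yc = 0.0, ys = 0.0, cc = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) {
      double a = w * (t[i] - tau);
      double co = std::cos(a), si = std::sin(a);
      yc += y[i] * co; ys += y[i] * si;
      cc += co * co;   ss += si * si;
    }
    double p = 0.0;
    if (cc > 0) p += yc * yc / cc;
    if (ss > 0) p += ys * ys / ss;
    out[k] = 0.5 * p;
  }
  return out;
}

// ------------------------------------------------------------ tree core
struct BNode {
  int feat = -1;       // -1: leaf
  double thr = 0.0;
  int left = -1, right = -1;
  double val = 0.0;    // node value (Newton step or class fraction)
};

struct Split {
  double gain = -1.0;
  int feat = -1;
  double thr = 0.0;
};

static inline double leaf_obj(double G, double H, double lambda) {
  return G * G / (H + lambda);
}

// Exact greedy best split for second-order boosting.
static Split best_split_gh(const NumericMatrix& X,
                           const std::vector<int>& idx,
                           const std::vector<double>& g,
                           const std::vector<double>& h,
                           double lambda, int min_leaf) {
  const int p = X.ncol();
  const int m = (int)idx.size();
  Split best;
  double G = 0, H = 0;
  for (int i = 0; i < m; ++i) { G += g[idx[i]]; H += h[idx[i]]; }
  double parent = leaf_obj(G, H, lambda);
  std::vector<int> ord(idx);
  for (int f = 0; f < p; ++f) {
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double GL = 0, HL = 0;
    for (int i = 0; i + 1 < m; ++i) {
      GL += g[ord[i]]; HL += h[ord[i]];
      if (X(ord[i], f) == X(ord[i + 1], f)) continue;
      if (i + 1 < min_leaf || m - i - 1 < min_leaf) continue;
      double gain = 0.5 * (leaf_obj(GL, HL, lambda) +
                           leaf_obj(G - GL, H - HL, lambda) - parent);
      if (gain > best.gain) {
        best.gain = gain;
        best.feat = f;
        best.thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
      }
    }
  }
  return best;
}

static List tree_to_list(const std::vector<BNode>& nodes) {
  const int m = (int)nodes.size();
  IntegerVector feat(m), left(m), right(m);
  NumericVector thr(m), val(m);
  for (int i = 0; i < m; ++i) {
    feat[i] = nodes[i].feat; thr[i] = nodes[i].thr;
    left[i] = nodes[i].left; right[i] = nodes[i].right;
    val[i] = nodes[i].val;
  }
  return List::create(_["feat"] = feat, _["thr"] = thr, _["left"] = left,
                      _["right"] = right, _["val"] = val);
}

// Grow one boosted tree. mode 0: level-wise to max_depth,
// mode 1: leaf-wise to max_leaves.
static List grow_tree_gh(const NumericMatrix& X,
                         const std::vector<double>& g,
                         const std::vector<double>& h,
                         double lambda, double lr, int max_depth,
                         int max_leaves, int mode, int min_leaf) {
  const int n = X.nrow();
  std::vector<BNode> nodes;
  struct Cand { int node; std::vector<int> idx; int depth; Split sp; };
  std::vector<Cand> open;
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  auto node_val = [&](const std::vector<int>& idx) {
    double G = 0, H = 0;
    for (int i : idx) { G += g[i]; H += h[i]; }
    return -G / (H + lambda) * lr;
  };
  nodes.push_back(BNode());
  nodes[0].val = node_val(all);
  open.push_back({0, all, 0, best_split_gh(X, all, g, h, lambda, min_leaf)});
  int n_leaves = 1;
  while (!open.empty()) {
    int pick = -1;
    if (mode == 1) {           // leaf-wise: split the best-gain leaf
      double bg = 1e-12;
      for (size_t k = 0; k < open.size(); ++k) {
        if (open[k].sp.gain > bg) { bg = open[k].sp.gain; pick = (int)k; }
      }
      if (pick < 0 || n_leaves >= max_leaves) break;
    } else {                   // level-wise: FIFO expansion
      pick = 0;
      Cand& c = open[0];
      if (c.depth >= max_depth || c.sp.gain <= 1e-12) {
        open.erase(open.begin());
        continue;
      }
    }
    Cand c = open[pick];
    open.erase(open.begin() + pick);
    if (c.sp.gain <= 1e-12) continue;
    std::vector<int> li, ri;
    for (int i : c.idx) {
      if (X(i, c.sp.feat) <= c.sp.thr) li.push_back(i);
      else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) continue;
    int lid = (int)nodes.size(), rid = lid + 1;
    nodes.push_back(BNode());
    nodes.push_back(BNode());
    nodes[c.node].feat = c.sp.feat;
    nodes[c.node].thr = c.sp.thr;
    nodes[c.node].left = lid;
    nodes[c.node].right = rid;
    nodes[lid].val = node_val(li);
    nodes[rid].val = node_val(ri);
    n_leaves += 1;
    int cd = c.depth + 1;
    bool deeper = (mode == 1) ? (cd < 30) : (cd < max_depth);
    Split sl = deeper ? best_split_gh(X, li, g, h, lambda, min_leaf) : Split();
    Split sr = deeper ? best_split_gh(X, ri, g, h, lambda, min_leaf) : Split();
    open.push_back({lid, li, cd, sl});
    open.push_back({rid, ri, cd, sr});
    if (mode == 1 && n_leaves >= max_leaves) break;
  }
  return tree_to_list(nodes);
}

// Oblivious (symmetric) tree on quantized features: one (feature,
// threshold) per depth level, shared by every node of that level.
static List grow_tree_oblivious(const NumericMatrix& X,
                                const IntegerMatrix& bins,
                                const List& borders,
                                const std::vector<double>& g,
                                const std::vector<double>& h,
                                double lambda, double lr, int depth) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> leaf(n, 0);
  std::vector<int> sel_feat;
  std::vector<double> sel_thr;
  int n_leaves = 1;
  for (int d = 0; d < depth; ++d) {
    double best_gain = 1e-12;
    int bf = -1, bb = -1;
    for (int f = 0; f < p; ++f) {
      NumericVector bor = borders[f];
      int nb = bor.size() + 1;
      if (nb < 2) continue;
      std::vector<double> HG(n_leaves * nb, 0.0), HH(n_leaves * nb, 0.0);
      for (int i = 0; i < n; ++i) {
        int cell = leaf[i] * nb + bins(i, f);
        HG[cell] += g[i]; HH[cell] += h[i];
      }
      for (int b = 0; b + 1 < nb; ++b) {
        double gain = 0.0;
        for (int l = 0; l < n_leaves; ++l) {
          double GL = 0, HL = 0, G = 0, H = 0;
          for (int bb2 = 0; bb2 < nb; ++bb2) {
            double gg = HG[l * nb + bb2], hh = HH[l * nb + bb2];
            G += gg; H += hh;
            if (bb2 <= b) { GL += gg; HL += hh; }
          }
          if (H <= 0) continue;
          gain += 0.5 * (leaf_obj(GL, HL, lambda) +
                         leaf_obj(G - GL, H - HL, lambda) -
                         leaf_obj(G, H, lambda));
        }
        if (gain > best_gain) { best_gain = gain; bf = f; bb = b; }
      }
    }
    if (bf < 0) break;
    NumericVector bor = borders[bf];
    sel_feat.push_back(bf);
    sel_thr.push_back(bor[bb]);
    for (int i = 0; i < n; ++i) {
      leaf[i] = leaf[i] * 2 + (bins(i, bf) > bb ? 1 : 0);
    }
    n_leaves *= 2;
  }
  // materialize as an ordinary binary tree with internal-node values
  int D = (int)sel_feat.size();
  int total = (1 << (D + 1)) - 1;
  std::vector<double> G(total, 0.0), H(total, 0.0);
  int first_leaf = (1 << D) - 1;
  for (int i = 0; i < (int)leaf.size(); ++i) {
    G[first_leaf + leaf[i]] += g[i];
    H[first_leaf + leaf[i]] += h[i];
  }
  for (int nd = first_leaf - 1; nd >= 0; --nd) {
    G[nd] = G[2 * nd + 1] + G[2 * nd + 2];
    H[nd] = H[2 * nd + 1] + H[2 * nd + 2];
  }
  std::vector<BNode> nodes(total);
  for (int nd = 0; nd < total; ++nd) {
    int lev = (int)std::floor(std::log2((double)nd + 1));
    nodes[nd].val = (H[nd] > 0) ? -G[nd] / (H[nd] + lambda) * lr
                                : (nd > 0 ? nodes[(nd - 1) / 2].val : 0.0);
    if (lev < D) {
      nodes[nd].feat = sel_feat[lev];
      nodes[nd].thr = sel_thr[lev];
      nodes[nd].left = 2 * nd + 1;
      nodes[nd].right = 2 * nd + 2;
    }
  }
  return tree_to_list(nodes);
}

static double tree_predict_row(const List& tree, const NumericMatrix& X,
                               int row) {
  IntegerVector feat = tree["feat"], left = tree["left"],
    right = tree["right"];
  NumericVector thr = tree["thr"], val = tree["val"];
  int nd = 0;
  while (feat[nd] >= 0) {
    nd = (X(row, feat[nd]) <= thr[nd]) ? left[nd] : right[nd];
  }
  return val[nd];
}

// [[Rcpp::export]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, int n_rounds,
                 double learning_rate, double lambda, int max_depth,
                 int max_leaves, int mode, int min_leaf,
                 double base_score) {
  const int n = X.nrow();
  std::vector<double> margin(n, base_score), g(n), h(n);
  List forest(n_rounds);
  IntegerMatrix bins;
  List borders;
  if (mode == 2) {             // quantize once for oblivious trees
    const int p = X.ncol(), max_bins = 64;
    bins = IntegerMatrix(n, p);
    borders = List(p);
    for (int f = 0; f < p; ++f) {
      std::vector<double> v(n);
      for (int i = 0; i < n; ++i) v[i] = X(i, f);
      std::sort(v.begin(), v.end());
      v.erase(std::unique(v.begin(), v.end()), v.end());
      std::vector<double> bor;
      int nu = (int)v.size();
      if (nu > 1) {
        int nb = std::min(max_bins, nu);
        for (int b = 1; b < nb; ++b) {
          int lo_i = (int)std::floor((double)b * nu / nb) - 1;
          if (lo_i < 0) lo_i = 0;
          int hi_i = std::min(lo_i + 1, nu - 1);
          double cut = 0.5 * (v[lo_i] + v[hi_i]);
          if (bor.empty() || cut > bor.back()) bor.push_back(cut);
        }
      }
      NumericVector bv(bor.begin(), bor.end());
      borders[f] = bv;
      for (int i = 0; i < n; ++i) {
        int b = 0;
        while (b < (int)bor.size() && X(i, f) > bor[b]) ++b;
        bins(i, f) = b;
      }
    }
  }
  for (int r = 0; r < n_rounds; ++r) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-16);
    }
    List tree = (mode == 2)
      ? grow_tree_oblivious(X, bins, borders, g, h, lambda,
                            learning_rate, max_depth)
      : grow_tree_gh(X, g, h, lambda, learning_rate, max_depth,
                     max_leaves, mode, min_leaf);
    for (int i = 0; i < n; ++i) margin[i] += tree_predict_row(tree, X, i);
    forest[r] = tree;
  }
  return List::create(_["trees"] = forest, _["base_score"] = base_score);
}

// [[Rcpp::export]]
NumericVector gbt_margin_cpp(List model, NumericMatrix X) {
  List forest = model["trees"];
  double base = as<double>(model["base_score"]);
  const int n = X.nrow();
  NumericVector out(n, base);
  for (int r = 0; r < forest.size(); ++r) {
    List tree = forest[r];
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(tree, X, i);
  }
  return out;
}

// Path attribution: walking each tree, the change in node value at
// every split is credited to the split feature. Summed (times
// `scale`) over trees, contributions satisfy
//   base + rowSums(contrib) == ensemble output, exactly.
// [[Rcpp::export]]
List path_contrib_cpp(List forest, NumericMatrix X, double scale) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix contrib(n, p);
  double base = 0.0;
  for (int r = 0; r < forest.size(); ++r) {
    List tree = forest[r];
    IntegerVector feat = tree["feat"], left = tree["left"],
      right = tree["right"];
    NumericVector thr = tree["thr"], val = tree["val"];
    base += scale * val[0];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (feat[nd] >= 0) {
        int nxt = (X(i, feat[nd]) <= thr[nd]) ? left[nd] : right[nd];
        contrib(i, feat[nd]) += scale * (val[nxt] - val[nd]);
        nd = nxt;
      }
    }
  }
  return List::create(_["contrib"] = contrib, _["base"] = base);
}

// ------------------------------------------------------- random forest
static Split best_split_gini(const NumericMatrix& X,
                             const std::vector<int>& idx,
                             const IntegerVector& y,
                             const std::vector<int>& feats,
                             int min_leaf) {
  const int m = (int)idx.size();
  Split best;
  double n1 = 0;
  for (int i : idx) n1 += y[i];
  double parent = 1.0 - (n1 / m) * (n1 / m) -
    ((m - n1) / m) * ((m - n1) / m);
  std::vector<int> ord(idx);
  for (int f : feats) {
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double l1 = 0;
    for (int i = 0; i + 1 < m; ++i) {
      l1 += y[ord[i]];
      if (X(ord[i], f) == X(ord[i + 1], f)) continue;
      double nl = i + 1, nr = m - nl, r1 = n1 - l1;
      if (nl < min_leaf || nr < min_leaf) continue;
      double gl = 1.0 - (l1 / nl) * (l1 / nl) -
        ((nl - l1) / nl) * ((nl - l1) / nl);
      double gr = 1.0 - (r1 / nr) * (r1 / nr) -
        ((nr - r1) / nr) * ((nr - r1) / nr);
      double gain = parent - (nl * gl + nr * gr) / m;
      if (gain > best.gain) {
        best.gain = gain;
        best.feat = f;
        best.thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
      }
    }
  }
  return best;
}

static void grow_rf_node(const NumericMatrix& X, const IntegerVector& y,
                         std::vector<BNode>& nodes, int node,
                         std::vector<int> idx, int mtry, int min_leaf,
                         int depth) {
  const int p = X.ncol();
  double n1 = 0;
  for (int i : idx) n1 += y[i];
  nodes[node].val = n1 / idx.size();
  if (n1 == 0 || n1 == (double)idx.size() ||
      (int)idx.size() < 2 * min_leaf || depth >= 30) return;
  // sample mtry features without replacement via R's RNG
  std::vector<int> pool(p);
  for (int f = 0; f < p; ++f) pool[f] = f;
  std::vector<int> feats;
  for (int k = 0; k < mtry && !pool.empty(); ++k) {
    int j = (int)(unif_rand() * pool.size());
    if (j >= (int)pool.size()) j = (int)pool.size() - 1;
    feats.push_back(pool[j]);
    pool.erase(pool.begin() + j);
  }
  Split sp = best_split_gini(X, idx, y, feats, min_leaf);
  if (sp.gain <= 1e-12) return;
  std::vector<int> li, ri;
  for (int i : idx) {
    if (X(i, sp.feat) <= sp.thr) li.push_back(i); else ri.push_back(i);
  }
  if (li.empty() || ri.empty()) return;
  int lid = (int)nodes.size(), rid = lid + 1;
  nodes.push_back(BNode());
  nodes.push_back(BNode());
  nodes[node].feat = sp.feat;
  nodes[node].thr = sp.thr;
  nodes[node].left = lid;
  nodes[node].right = rid;
  grow_rf_node(X, y, nodes, lid, li, mtry, min_leaf, depth + 1);
  grow_rf_node(X, y, nodes, rid, ri, mtry, min_leaf, depth + 1);
}

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_leaf) {
  RNGScope scope;
  const int n = X.nrow();
  List forest(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      idx[i] = (j >= n) ? n - 1 : j;
    }
    std::vector<BNode> nodes(1);
    grow_rf_node(X, y, nodes, 0, idx, mtry, min_leaf, 0);
    forest[t] = tree_to_list(nodes);
  }
  return List::create(_["trees"] = forest);
}

// [[Rcpp::export]]
NumericVector rf_prob_cpp(List model, NumericMatrix X) {
  List forest = model["trees"];
  const int n = X.nrow();
  NumericVector out(n, 0.0);
  for (int t = 0; t < forest.size(); ++t) {
    List tree = forest[t];
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(tree, X, i);
  }
  return out / (double)forest.size();
}

// ------------------------------------------------------------ SVM (SMO)
static double rbf(const NumericMatrix& A, int i, const NumericMatrix& B,
                  int j, double gamma) {
  double d = 0.0;
  for (int k = 0; k < A.ncol(); ++k) {
    double z = A(i, k) - B(j, k);
    d += z * z;
  }
  return std::exp(-gamma * d);
}

// Simplified sequential minimal optimization for the soft-margin RBF
// SVM dual; second index chosen uniformly at random via R's RNG.
// [[Rcpp::export]]
List svm_fit_cpp(NumericMatrix X, NumericVector y, double C, double gamma,
                 double tol, int max_passes) {
  RNGScope scope;
  const int n = X.nrow();
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      K(i, j) = K(j, i) = rbf(X, i, X, j, gamma);
    }
  }
  std::vector<double> alpha(n, 0.0);
  double b = 0.0;
  auto fx = [&](int i) {
    double s = b;
    for (int j = 0; j < n; ++j) {
      if (alpha[j] != 0.0) s += alpha[j] * y[j] * K(i, j);
    }
    return s;
  };
  int passes = 0, iter_guard = 0;
  while (passes < max_passes && iter_guard < 200) {
    ++iter_guard;
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double Ei = fx(i) - y[i];
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        int j = (int)(unif_rand() * (n - 1));
        if (j >= i) ++j;
        if (j >= n) j = n - 1;
        double Ej = fx(j) - y[j];
        double ai = alpha[i], aj = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          L = std::max(0.0, aj - ai);
          H = std::min(C, C + aj - ai);
        } else {
          L = std::max(0.0, ai + aj - C);
          H = std::min(C, ai + aj);
        }
        if (L >= H) continue;
        double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
        if (eta >= 0) continue;
        double ajn = aj - y[j] * (Ei - Ej) / eta;
        ajn = std::min(H, std::max(L, ajn));
        if (std::fabs(ajn - aj) < 1e-6) continue;
        double ain = ai + y[i] * y[j] * (aj - ajn);
        double b1 = b - Ei - y[i] * (ain - ai) * K(i, i) -
          y[j] * (ajn - aj) * K(i, j);
        double b2 = b - Ej - y[i] * (ain - ai) * K(i, j) -
          y[j] * (ajn - aj) * K(j, j);
        alpha[i] = ain;
        alpha[j] = ajn;
        if (ain > 0 && ain < C) b = b1;
        else if (ajn > 0 && ajn < C) b = b2;
        else b = 0.5 * (b1 + b2);
        ++changed;
      }
    }
    passes = changed ? 0 : passes + 1;
  }
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b);
}

// [[Rcpp::export]]
NumericVector svm_decision_cpp(NumericMatrix Xtrain, NumericVector y,
                               NumericVector alpha, double b, double gamma,
                               NumericMatrix Xnew) {
  const int m = Xnew.nrow(), n = Xtrain.nrow();
  NumericVector out(m, b);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      if (alpha[j] != 0.0) {
        out[i] += alpha[j] * y[j] * rbf(Xnew, i, Xtrain, j, gamma);
      }
    }
  }
  return out;
}
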