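// CART classification trees with Gini impurity, exact split enumeration,
// per-node random feature subsampling, and a bagged forest built on top.
// Trees are returned to R as flat parallel arrays (node -1 child = leaf
// marker is encoded by left < 0).

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature, left, right;
  std::vector<double> threshold;
  std::vector<std::vector<double>> proba;  // per-node class distribution
};

double gini_from_counts(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (int c : cnt) {
    double p = static_cast<double>(c) / n;
    s += p * p;
  }
  return 1.0 - s;
}

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  int K, max_depth, min_split, min_leaf, mtry;
  std::mt19937 rng;
  TreeBuf buf;
  std::vector<int> feat_pool;

  Grower(const NumericMatrix& X_, const IntegerVector& y_, int K_,
         int max_depth_, int min_split_, int min_leaf_, int mtry_,
         unsigned int seed)
      : X(X_), y(y_), K(K_), max_depth(max_depth_), min_split(min_split_),
        min_leaf(min_leaf_), mtry(mtry_), rng(seed) {
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  int make_leaf(const std::vector<int>& cnt, int n) {
    int id = static_cast<int>(buf.feature.size());
    buf.feature.push_back(-1);
    buf.threshold.push_back(0.0);
    buf.left.push_back(-1);
    buf.right.push_back(-1);
    std::vector<double> p(K);
    for (int c = 0; c < K; ++c) p[c] = static_cast<double>(cnt[c]) / n;
    buf.proba.push_back(p);
    return id;
  }

  int grow(std::vector<int>& idx, int depth) {
    int n = static_cast<int>(idx.size());
    std::vector<int> cnt(K, 0);
    for (int i : idx) ++cnt[y[i]];
    int nz = 0;
    for (int c = 0; c < K; ++c) nz += (cnt[c] > 0);
    if (depth >= max_depth || n < min_split || nz <= 1 || n < 2 * min_leaf)
      return make_leaf(cnt, n);

    // random feature subset (partial Fisher-Yates)
    int p = static_cast<int>(feat_pool.size());
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feat_pool[j], feat_pool[d(rng)]);
    }

    double best_score = -1.0;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(n);
    double parent_imp = gini_from_counts(cnt, n);

    for (int jj = 0; jj < m; ++jj) {
      int f = feat_pool[jj];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::vector<int> lc(K, 0);
      for (int i = 1; i < n; ++i) {
        ++lc[vals[i - 1].second];
        if (vals[i].first == vals[i - 1].first) continue;
        int nl = i, nr = n - i;
        if (nl < min_leaf || nr < min_leaf) continue;
        double gl = 0.0, gr = 0.0;
        for (int c = 0; c < K; ++c) {
          double pl = static_cast<double>(lc[c]) / nl;
          double pr = static_cast<double>(cnt[c] - lc[c]) / nr;
          gl += pl * pl;
          gr += pr * pr;
        }
        double imp = (nl * (1.0 - gl) + nr * (1.0 - gr)) / n;
        double score = parent_imp - imp;
        if (score > best_score + 1e-12) {
          best_score = score;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i - 1].first);
        }
      }
    }
    if (best_f < 0 || best_score <= 1e-12) return make_leaf(cnt, n);

    std::vector<int> li, ri;
    li.reserve(n);
    ri.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i);
      else ri.push_back(i);
    }
    int id = static_cast<int>(buf.feature.size());
    buf.feature.push_back(best_f);
    buf.threshold.push_back(best_thr);
    buf.left.push_back(-2);   // patched below
    buf.right.push_back(-2);
    buf.proba.push_back(std::vector<double>(K, 0.0));
    int lid = grow(li, depth + 1);
    int rid = grow(ri, depth + 1);
    buf.left[id] = lid;
    buf.right[id] = rid;
    return id;
  }
};

List pack_tree(const TreeBuf& buf, int K) {
  int nn = static_cast<int>(buf.feature.size());
  NumericMatrix P(nn, K);
  for (int i = 0; i < nn; ++i)
    for (int c = 0; c < K; ++c) P(i, c) = buf.proba[i][c];
  return List::create(_["feature"] = wrap(buf.feature),
                      _["threshold"] = wrap(buf.threshold),
                      _["left"] = wrap(buf.left),
                      _["right"] = wrap(buf.right), _["proba"] = P);
}

void predict_into(const List& tree, const NumericMatrix& X, NumericMatrix& out,
                  double weight) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  NumericMatrix proba = tree["proba"];
  int K = proba.ncol();
  for (int i = 0; i < X.nrow(); ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    for (int c = 0; c < K; ++c) out(i, c) += weight * proba(node, c);
  }
}

}  // namespace

// [[Rcpp::export]]
List fit_cart_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                  int max_depth, int min_split, int min_leaf, int mtry,
                  int seed, IntegerVector sample_idx) {
  if (max_depth <= 0) max_depth = 1000000000;
  if (min_split < 2) min_split = 2;
  if (min_leaf < 1) min_leaf = 1;
  Grower g(X, y, n_classes, max_depth, min_split, min_leaf, mtry,
           static_cast<unsigned int>(seed));
  std::vector<int> idx(sample_idx.begin(), sample_idx.end());
  g.grow(idx, 0);
  return pack_tree(g.buf, n_classes);
}

// [[Rcpp::export]]
NumericMatrix predict_cart_cpp(List tree, NumericMatrix X) {
  NumericMatrix proba = tree["proba"];
  NumericMatrix out(X.nrow(), proba.ncol());
  predict_into(tree, X, out, 1.0);
  return out;
}

// [[Rcpp::export]]
List fit_forest_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                    int n_estimators, int max_depth, int min_split,
                    int min_leaf, int mtry, int seed) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  int n = X.nrow();
  std::uniform_int_distribution<int> pick(0, n - 1);
  List trees(n_estimators);
  for (int b = 0; b < n_estimators; ++b) {
    IntegerVector idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    unsigned int tree_seed = rng();
    trees[b] = fit_cart_cpp(X, y, n_classes, max_depth, min_split, min_leaf,
                            mtry, static_cast<int>(tree_seed % 2147483647),
                            idx);
  }
  return trees;
}

// [[Rcpp::export]]
NumericMatrix predict_forest_cpp(List trees, NumericMatrix X, int n_classes) {
  NumericMatrix out(X.nrow(), n_classes);
  double w = 1.0 / trees.size();
  for (int b = 0; b < trees.size(); ++b) {
    List tree = trees[b];
    predict_into(tree, X, out, w);
  }
  return out;
}
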