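// Random forest of CART classification trees.
//
// Standard Breiman construction: each tree is grown on a bootstrap sample of
// the training rows; at every node the best Gini split is chosen among `mtry`
// features drawn at random; trees are grown to purity (min_node = 1 by
// default) and vote at prediction time. Variable importance is the mean
// (over trees) total impurity decrease contributed by each feature, weighted
// by the fraction of samples reaching the node. All randomness comes from
// R's RNG so results are reproducible with set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct TreeBuf {
  std::vector<int> feature, left, right, leaf;
  std::vector<double> thr;
};

static double gini_from_counts(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int c : cnt) {
    double p = (double)c / n;
    g -= p * p;
  }
  return g;
}

static int majority(const std::vector<int>& cnt) {
  int best = 0;
  for (size_t k = 1; k < cnt.size(); ++k)
    if (cnt[k] > cnt[best]) best = (int)k; // ties keep lowest class id
  return best;
}

static int build_node(const NumericMatrix& X, const IntegerVector& y,
                      int n_classes, int mtry, int min_node,
                      std::vector<int>& rows, TreeBuf& T,
                      std::vector<double>& importance, int n_total) {
  const int n = (int)rows.size();
  std::vector<int> cnt(n_classes, 0);
  for (int i : rows) cnt[y[i]]++;
  double g0 = gini_from_counts(cnt, n);
  int node = (int)T.feature.size();
  T.feature.push_back(-1); T.thr.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1);
  T.leaf.push_back(majority(cnt));
  if (n <= min_node || g0 <= 0.0) return node;

  const int p = X.ncol();
  // draw mtry distinct candidate features (partial Fisher-Yates, R RNG)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int pick = j + (int)(unif_rand() * (p - j));
    if (pick >= p) pick = p - 1;
    std::swap(feats[j], feats[pick]);
  }

  int best_f = -1; double best_thr = 0.0, best_gain = 0.0;
  std::vector<int> ord(n);
  std::vector<int> lcnt(n_classes);
  for (int j = 0; j < m; ++j) {
    int f = feats[j];
    for (int i = 0; i < n; ++i) ord[i] = rows[i];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (X(a, f) != X(b, f)) return X(a, f) < X(b, f);
      return a < b;
    });
    std::fill(lcnt.begin(), lcnt.end(), 0);
    int nl = 0;
    for (int i = 0; i < n - 1; ++i) {
      lcnt[y[ord[i]]]++; nl++;
      if (X(ord[i], f) == X(ord[i + 1], f)) continue;
      int nr = n - nl;
      double gl = 1.0, gr = 1.0;
      // right counts = cnt - lcnt
      gl = 0.0; gr = 0.0;
      for (int k = 0; k < n_classes; ++k) {
        double pl = (double)lcnt[k] / nl;
        double pr = (double)(cnt[k] - lcnt[k]) / nr;
        gl += pl * pl; gr += pr * pr;
      }
      gl = 1.0 - gl; gr = 1.0 - gr;
      double gain = g0 - ((double)nl / n) * gl - ((double)nr / n) * gr;
      if (gain > best_gain + 1e-15) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
      }
    }
  }
  if (best_f < 0) return node; // no informative split among candidates

  importance[best_f] += ((double)n / n_total) * best_gain;
  std::vector<int> lrows, rrows;
  lrows.reserve(n); rrows.reserve(n);
  for (int i : rows) {
    if (X(i, best_f) <= best_thr) lrows.push_back(i); else rrows.push_back(i);
  }
  if (lrows.empty() || rrows.empty()) return node; // numeric degeneracy
  T.feature[node] = best_f;
  T.thr[node] = best_thr;
  rows.clear(); rows.shrink_to_fit();
  int L = build_node(X, y, n_classes, mtry, min_node, lrows, T, importance, n_total);
  T.left[node] = L;
  int R = build_node(X, y, n_classes, mtry, min_node, rrows, T, importance, n_total);
  T.right[node] = R;
  return node;
}

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                  int ntree, int mtry, int min_node) {
  const int n = X.nrow();
  List trees(ntree);
  std::vector<double> importance(X.ncol(), 0.0);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      int pick = (int)(unif_rand() * n);
      if (pick >= n) pick = n - 1;
      rows[i] = pick;
    }
    IntegerVector inbag(rows.begin(), rows.end()); // 0-based bootstrap picks
    TreeBuf T;
    build_node(X, y, n_classes, mtry, min_node, rows, T, importance, n);
    trees[t] = List::create(_["feature"] = wrap(T.feature),
                            _["thr"] = wrap(T.thr),
                            _["left"] = wrap(T.left),
                            _["right"] = wrap(T.right),
                            _["leaf"] = wrap(T.leaf),
                            _["inbag"] = inbag);
  }
  NumericVector imp(importance.begin(), importance.end());
  imp = imp / (double)ntree;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".rf_votes_cpp")]]
IntegerMatrix rf_votes_cpp(List trees, NumericMatrix X, int n_classes) {
  const int n = X.nrow(), ntree = trees.size();
  IntegerMatrix votes(n, n_classes);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
      right = tr["right"], leaf = tr["leaf"];
    NumericVector thr = tr["thr"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= thr[node]) ? left[node] : right[node];
      }
      votes(i, leaf[node])++;
    }
  }
  return votes;
}
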