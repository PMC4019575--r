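// Region-growing segmentation of a single-band raster.
//
// Every valid pixel starts as its own region. The algorithm repeatedly merges
// the adjacent (4-connected) region pair whose region means differ least,
// provided the difference is below the current threshold; the threshold ramps
// geometrically over `n_passes` passes up to the user threshold ("increasingly
// less stringent"). A final phase merges every region smaller than
// `area_threshold` pixels into its most similar adjacent region. Ties are
// broken by lower region id, so output is fully deterministic.

#include <Rcpp.h>
#include <queue>
#include <set>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Edge {
  double diff;
  int a, b; // root ids at push time, a < b
};
struct EdgeCmp {
  bool operator()(const Edge& x, const Edge& y) const {
    if (x.diff != y.diff) return x.diff > y.diff; // min-heap on diff
    if (x.a != y.a) return x.a > y.a;
    return x.b > y.b;
  }
};

static std::vector<int> parent_;

static int find_root(int x) {
  while (parent_[x] != x) {
    parent_[x] = parent_[parent_[x]];
    x = parent_[x];
  }
  return x;
}

// [[Rcpp::export(name = ".region_grow_cpp")]]
List region_grow_cpp(NumericMatrix img, double similarity_threshold,
                     int area_threshold, int n_passes) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<double> sum(n, 0.0);
  std::vector<int> size(n, 0);
  std::vector<char> valid(n, 0);
  parent_.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    parent_[i] = i;
    if (!NumericMatrix::is_na(img[i])) {
      valid[i] = 1;
      sum[i] = img[i];
      size[i] = 1;
    }
  }
  // adjacency sets between roots (4-connected)
  std::vector< std::set<int> > nbr(n);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      if (!valid[i]) continue;
      if (r + 1 < nr && valid[i + 1]) { nbr[i].insert(i + 1); nbr[i + 1].insert(i); }
      if (c + 1 < nc && valid[i + nr]) { nbr[i].insert(i + nr); nbr[i + nr].insert(i); }
    }
  }
  auto mean_of = [&](int r) { return sum[r] / size[r]; };
  auto merge = [&](int a, int b) -> int { // returns surviving root (min id)
    int keep = std::min(a, b), drop = std::max(a, b);
    parent_[drop] = keep;
    sum[keep] += sum[drop];
    size[keep] += size[drop];
    for (int x : nbr[drop]) {
      if (x == keep) continue;
      nbr[x].erase(drop);
      nbr[x].insert(keep);
      nbr[keep].insert(x);
    }
    nbr[keep].erase(drop);
    nbr[keep].erase(keep);
    nbr[drop].clear();
    return keep;
  };

  if (n_passes < 1) n_passes = 1;
  for (int pass = 1; pass <= n_passes; ++pass) {
    double thr = similarity_threshold * std::pow(2.0, (double)(pass - n_passes));
    std::priority_queue<Edge, std::vector<Edge>, EdgeCmp> heap;
    for (int i = 0; i < n; ++i) {
      if (!valid[i] || parent_[i] != i) continue;
      for (int x : nbr[i]) {
        if (x > i) {
          double d = std::fabs(mean_of(i) - mean_of(x));
          if (d < thr) heap.push({d, i, x});
        }
      }
    }
    while (!heap.empty()) {
      Edge e = heap.top(); heap.pop();
      int ra = find_root(e.a), rb = find_root(e.b);
      if (ra == rb) continue;
      int a = std::min(ra, rb), b = std::max(ra, rb);
      if (!nbr[a].count(b)) continue; // stale edge
      double d = std::fabs(mean_of(a) - mean_of(b));
      if (d >= thr) continue;
      if (d > e.diff + 1e-15 || a != e.a || b != e.b) {
        // means moved since push (or roots renamed): reinsert with fresh key
        heap.push({d, a, b});
        continue;
      }
      int keep = merge(a, b);
      for (int x : nbr[keep]) {
        double dn = std::fabs(mean_of(keep) - mean_of(x));
        if (dn < thr)
          heap.push({dn, std::min(keep, x), std::max(keep, x)});
      }
    }
  }

  // area-threshold phase: absorb small regions into most similar neighbour
  if (area_threshold > 1) {
    std::set<int> blocked; // small regions with no neighbours (nodata islands)
    for (;;) {
      int worst = -1;
      for (int i = 0; i < n; ++i) {
        if (!valid[i] || parent_[i] != i) continue;
        if (size[i] >= area_threshold || blocked.count(i)) continue;
        if (worst < 0 || size[i] < size[worst] ||
            (size[i] == size[worst] && i < worst)) worst = i;
      }
      if (worst < 0) break;
      if (nbr[worst].empty()) { blocked.insert(worst); continue; }
      int best = -1; double bestd = 0.0;
      for (int x : nbr[worst]) {
        double d = std::fabs(mean_of(worst) - mean_of(x));
        if (best < 0 || d < bestd || (d == bestd && x < best)) { best = x; bestd = d; }
      }
      merge(worst, best);
    }
  }

  // relabel surviving roots 1..K in order of first pixel (column-major)
  IntegerVector labels(n, NA_INTEGER);
  std::vector<int> newid(n, 0);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (!valid[i]) continue;
    int r = find_root(i);
    if (newid[r] == 0) newid[r] = ++k;
    labels[i] = newid[r];
  }
  IntegerVector areas(k);
  NumericVector means(k);
  for (int i = 0; i < n; ++i) {
    if (!valid[i] || parent_[i] != i) continue;
    int id = newid[i] - 1;
    areas[id] = size[i];
    means[id] = mean_of(i);
  }
  labels.attr("dim") = Dimension(nr, nc);
  return List::create(_["labels"] = labels, _["areas"] = areas,
                      _["means"] = means, _["n_segments"] = k);
}
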