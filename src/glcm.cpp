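// Sliding-window grey-level co-occurrence texture features.
//
// For each pixel, a square window is examined in the four standard
// displacement directions (0, 45, 90, 135 degrees; displacement 1). Pairs are
// counted symmetrically into a normalized GLCM P and three Haralick features
// are extracted -- homogeneity sum P/(1+(i-j)^2), entropy -sum P ln P, and
// correlation sum (i-mu)(j-mu)P / sigma^2 (0 when sigma = 0) -- then averaged
// over the four directions. Windows touching the image border or any nodata
// pixel emit nodata. Grey levels are used as-is (0-255, no requantisation).

#include <Rcpp.h>
#include <map>
#include <cmath>
using namespace Rcpp;

static void dir_features(const IntegerMatrix& img, int r0, int c0, int half,
                         int dr, int dc, double out[3]) {
  std::map<std::pair<int,int>, double> cnt;
  double total = 0.0;
  for (int c = c0 - half; c <= c0 + half; ++c) {
    for (int r = r0 - half; r <= r0 + half; ++r) {
      int r2 = r + dr, c2 = c + dc;
      if (r2 < r0 - half || r2 > r0 + half || c2 < c0 - half || c2 > c0 + half)
        continue;
      int g1 = img(r, c), g2 = img(r2, c2);
      cnt[{g1, g2}] += 1.0;
      cnt[{g2, g1}] += 1.0;
      total += 2.0;
    }
  }
  double hom = 0.0, ent = 0.0, mu = 0.0;
  for (auto& kv : cnt) {
    double p = kv.second / total;
    int i = kv.first.first, j = kv.first.second;
    hom += p / (1.0 + (double)(i - j) * (i - j));
    ent -= p * std::log(p);
    mu += p * i;
  }
  double var = 0.0, cov = 0.0;
  for (auto& kv : cnt) {
    double p = kv.second / total;
    double di = kv.first.first - mu, dj = kv.first.second - mu;
    var += p * di * di;
    cov += p * di * dj;
  }
  out[0] = hom;
  out[1] = ent;
  out[2] = (var > 0.0) ? cov / var : 0.0;
}

// [[Rcpp::export(name = ".glcm_features_cpp")]]
List glcm_features_cpp(IntegerMatrix img, int window) {
  const int nr = img.nrow(), nc = img.ncol();
  const int half = window / 2;
  NumericMatrix hom(nr, nc), ent(nr, nc), cor(nr, nc);
  std::fill(hom.begin(), hom.end(), NA_REAL);
  std::fill(ent.begin(), ent.end(), NA_REAL);
  std::fill(cor.begin(), cor.end(), NA_REAL);
  const int dirs[4][2] = {{0, 1}, {-1, 1}, {-1, 0}, {-1, -1}};
  for (int c = half; c < nc - half; ++c) {
    for (int r = half; r < nr - half; ++r) {
      bool ok = true;
      for (int cc = c - half; cc <= c + half && ok; ++cc)
        for (int rr = r - half; rr <= r + half; ++rr)
          if (IntegerMatrix::is_na(img(rr, cc))) { ok = false; break; }
      if (!ok) continue;
      double acc[3] = {0, 0, 0}, f[3];
      for (int d = 0; d < 4; ++d) {
        dir_features(img, r, c, half, dirs[d][0], dirs[d][1], f);
        acc[0] += f[0]; acc[1] += f[1]; acc[2] += f[2];
      }
      hom(r, c) = acc[0] / 4.0;
      ent(r, c) = acc[1] / 4.0;
      cor(r, c) = acc[2] / 4.0;
    }
  }
  return List::create(_["homogeneity"] = hom, _["entropy"] = ent,
                      _["correlation"] = cor);
}
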