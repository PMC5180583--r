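#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// symmetric (mirror, edge duplicated) reflection of an out-of-range index:
// ... 1 0 | 0 1 ... n-1 | n-1 n-2 ...
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - 1 - i;
}

// Local Shannon entropy (bits) of the 256-bin histogram of 8-bit values in
// the structuring-element neighbourhood of every pixel. Excluded pixels are
// dropped from every histogram they would contribute to; an excluded centre
// gets entropy 0. Borders are handled by mirror reflection.
// img: integer matrix with values in [0, 255]; offs: K x 2 (row, col)
// displacements; excl: logical matrix, TRUE = excluded ("deleted").
// [[Rcpp::export]]
NumericMatrix local_entropy_cpp(IntegerMatrix img, IntegerMatrix offs,
                                LogicalMatrix excl) {
  const int nr = img.nrow(), nc = img.ncol(), K = offs.nrow();
  if (excl.nrow() != nr || excl.ncol() != nc)
    stop("exclusion mask dimensions do not match the image");
  NumericMatrix out(nr, nc);
  std::vector<int> doff(K), coff(K);
  for (int k = 0; k < K; ++k) { doff[k] = offs(k, 0); coff[k] = offs(k, 1); }
  std::vector<int> hist(256);
  const double inv_log2 = 1.0 / std::log(2.0);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (excl(i, j)) { out(i, j) = 0.0; continue; }
      std::fill(hist.begin(), hist.end(), 0);
      int n = 0;
      for (int k = 0; k < K; ++k) {
        const int ii = reflect_idx(i + doff[k], nr);
        const int jj = reflect_idx(j + coff[k], nc);
        if (excl(ii, jj)) continue;
        const int v = img(ii, jj);
        if (v < 0 || v > 255) stop("image values must lie in [0, 255]");
        ++hist[v];
        ++n;
      }
      if (n == 0) { out(i, j) = 0.0; continue; }
      double h = 0.0;
      const double dn = (double)n;
      for (int v = 0; v < 256; ++v) {
        if (hist[v]) {
          const double p = hist[v] / dn;
          h -= p * std::log(p) * inv_log2;
        }
      }
      out(i, j) = h;
    }
  }
  return out;
}

// 8-connected component labelling of a binary mask; labels 1..K in
// first-encounter (column-major) order, background 0.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        const int ci = stack.back().first, cj = stack.back().second;
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              stack.push_back(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
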