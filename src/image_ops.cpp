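#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// symmetric (half-sample) reflection into [0, n)
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian blur, kernel truncated at +/- 4 sigma, reflect boundary.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& img, double sigma) {
  int ny = img.nrow(), nx = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (size_t u = 0; u < k.size(); ++u) k[u] /= s;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int j = 0; j < nx; ++j)          // vertical pass (slow axis)
    for (int i = 0; i < ny; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) acc += k[t + r] * img(refl(i + t, ny), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nx; ++j)          // horizontal pass (fast axis)
    for (int i = 0; i < ny; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) acc += k[t + r] * tmp(i, refl(j + t, nx));
      out(i, j) = acc;
    }
  return out;
}

// 2x2 mean downsampling (odd trailing row/column dropped).
// [[Rcpp::export]]
NumericMatrix cpp_downsample2(const NumericMatrix& img) {
  int ny = img.nrow() / 2, nx = img.ncol() / 2;
  NumericMatrix out(ny, nx);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i)
      out(i, j) = 0.25 * (img(2 * i, j * 2) + img(2 * i + 1, 2 * j) +
                          img(2 * i, 2 * j + 1) + img(2 * i + 1, 2 * j + 1));
  return out;
}

// Strict 3x3 local maxima of img where valid(i,j); plateau ties broken so the
// lexicographically smallest (row, col) position wins. Returns 1-based (y, x).
// [[Rcpp::export]]
IntegerMatrix cpp_local_max2(const NumericMatrix& img, const LogicalMatrix& valid) {
  int ny = img.nrow(), nx = img.ncol();
  std::vector<int> ys, xs;
  for (int i = 1; i < ny - 1; ++i)
    for (int j = 1; j < nx - 1; ++j) {
      if (!valid(i, j)) continue;
      double c = img(i, j);
      bool ok = true;
      for (int di = -1; di <= 1 && ok; ++di)
        for (int dj = -1; dj <= 1 && ok; ++dj) {
          if (di == 0 && dj == 0) continue;
          double v = img(i + di, j + dj);
          bool earlier = (di < 0) || (di == 0 && dj < 0);
          if (earlier ? (c <= v) : (c < v)) ok = false;
        }
      if (ok) { ys.push_back(i + 1); xs.push_back(j + 1); }
    }
  IntegerMatrix out(ys.size(), 2);
  for (size_t t = 0; t < ys.size(); ++t) { out(t, 0) = ys[t]; out(t, 1) = xs[t]; }
  return out;
}

// Strict 3x3x3 maxima of a (ny, nx, ns) stack, interior in all dimensions,
// above `threshold`, excluding positions where !valid. Returns 1-based (y, x, s).
// [[Rcpp::export]]
IntegerMatrix cpp_local_max3(const NumericVector& arr, const LogicalMatrix& valid,
                             double threshold) {
  IntegerVector dims = arr.attr("dim");
  int ny = dims[0], nx = dims[1], ns = dims[2];
  const double* a = &arr[0];
  std::vector<int> ys, xs, ss;
  for (int s = 1; s < ns - 1; ++s)
    for (int j = 1; j < nx - 1; ++j)
      for (int i = 1; i < ny - 1; ++i) {
        if (!valid(i, j)) continue;
        double c = a[i + ny * (j + (size_t)nx * s)];
        if (!(c > threshold)) continue;
        bool ok = true;
        for (int ds = -1; ds <= 1 && ok; ++ds)
          for (int di = -1; di <= 1 && ok; ++di)
            for (int dj = -1; dj <= 1 && ok; ++dj) {
              if (ds == 0 && di == 0 && dj == 0) continue;
              double v = a[(i + di) + ny * ((j + dj) + (size_t)nx * (s + ds))];
              bool earlier = (ds < 0) || (ds == 0 && (di < 0 || (di == 0 && dj < 0)));
              if (earlier ? (c <= v) : (c < v)) ok = false;
            }
        if (ok) { ys.push_back(i + 1); xs.push_back(j + 1); ss.push_back(s + 1); }
      }
  IntegerMatrix out(ys.size(), 3);
  for (size_t t = 0; t < ys.size(); ++t) {
    out(t, 0) = ys[t]; out(t, 1) = xs[t]; out(t, 2) = ss[t];
  }
  return out;
}

// 8-connected component labelling of a logical matrix; labels 1..K, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& m) {
  int ny = m.nrow(), nx = m.ncol();
  IntegerMatrix lab(ny, nx);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j0 = 0; j0 < nx; ++j0)
    for (int i0 = 0; i0 < ny; ++i0) {
      if (!m(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i0, j0));
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
            if (m(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
      }
    }
  return lab;
}
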