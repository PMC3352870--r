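#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Reflect an out-of-range index back into [0, n-1] (half-sample symmetry,
// i.e. -1 -> 0, n -> n-1), matching reflect padding of the image border.
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Convolve every column of img (depth axis) with a 1-D kernel, reflect
// padding; borders use reflected indices, the interior runs unchecked.
static void conv_depth(const NumericMatrix& img, const NumericVector& kernel,
                       NumericMatrix& out) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = kernel.size() / 2;
  for (int j = 0; j < nc; ++j) {
    const double* col = &img(0, j);
    double* o = &out(0, j);
    const int lo = std::min(r, nr), hi = std::max(lo, nr - r);
    for (int i = 0; i < lo; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) acc += kernel[t + r] * col[reflect_idx(i + t, nr)];
      o[i] = acc;
    }
    for (int i = lo; i < hi; ++i) {
      double acc = 0.0;
      const double* p = col + i - r;
      for (int t = 0; t < 2 * r + 1; ++t) acc += kernel[t] * p[t];
      o[i] = acc;
    }
    for (int i = hi; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) acc += kernel[t + r] * col[reflect_idx(i + t, nr)];
      o[i] = acc;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix conv_depth_cpp(NumericMatrix img, NumericVector kernel) {
  NumericMatrix out(img.nrow(), img.ncol());
  conv_depth(img, kernel, out);
  return out;
}

// Separable convolution with a symmetric 1-D kernel along both axes,
// reflect padding: convolve columns, transpose, convolve again, transpose.
// [[Rcpp::export]]
NumericMatrix sep_conv_cpp(NumericMatrix img, NumericVector kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc);
  conv_depth(img, kernel, tmp);
  NumericMatrix tt = transpose(tmp);
  NumericMatrix tout(nc, nr);
  conv_depth(tt, kernel, tout);
  return transpose(tout);
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int window) {
  const int nr = img.nrow(), nc = img.ncol(), r = window / 2;
  NumericMatrix out(nr, nc);
  const int wlen = window * window;
  std::vector<double> buf(wlen);
  std::vector<const double*> cols(window);
  for (int j = 0; j < nc; ++j) {
    for (int dj = -r; dj <= r; ++dj) {
      cols[dj + r] = &img(0, reflect_idx(j + dj, nc));
    }
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      if (i >= r && i < nr - r) {
        for (int c = 0; c < window; ++c) {
          const double* p = cols[c] + i - r;
          for (int t = 0; t < window; ++t) buf[k++] = p[t];
        }
      } else {
        for (int c = 0; c < window; ++c) {
          for (int di = -r; di <= r; ++di) {
            buf[k++] = cols[c][reflect_idx(i + di, nr)];
          }
        }
      }
      std::nth_element(buf.begin(), buf.begin() + wlen / 2, buf.end());
      out(i, j) = buf[wlen / 2];
    }
  }
  return out;
}
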