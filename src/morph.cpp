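#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Flat grayscale morphology along image rows/columns with the image border
// treated as background (value 0, dark field). Erosion uses a left-anchored
// window (indices x..x+k-1), dilation the reflected window (x-k+1..x), so the
// composition dilate(erode(.)) is a proper algebraic opening for any window
// length k, even or odd.

// sliding min of f[x..x+k-1]; windows reaching past the end include the
// 0-valued background, and since f >= 0 the result there is 0
static void erode_vec(const double *f, double *out, int n, int k, int stride) {
  if (k >= n + 1) { // window never fits without touching background on both sides
    for (int x = 0; x < n; ++x) out[x * stride] = 0.0;
    return;
  }
  std::deque<int> dq;
  for (int i = 0; i < n; ++i) {
    double v = f[i * stride];
    while (!dq.empty() && f[dq.back() * stride] >= v) dq.pop_back();
    dq.push_back(i);
    int x = i - k + 1; // window [x, i]
    if (x >= 0) {
      while (dq.front() < x) dq.pop_front();
      out[x * stride] = f[dq.front() * stride];
    }
  }
  for (int x = n - k + 1; x < n; ++x)
    if (x >= 0) out[x * stride] = 0.0;
}

// sliding max of g[x-k+1..x]; out-of-range positions hold background 0,
// which never exceeds g >= 0, so they are simply skipped
static void dilate_vec(const double *g, double *out, int n, int k, int stride) {
  std::deque<int> dq;
  for (int x = 0; x < n; ++x) {
    double v = g[x * stride];
    while (!dq.empty() && g[dq.back() * stride] <= v) dq.pop_back();
    dq.push_back(x);
    while (dq.front() < x - k + 1) dq.pop_front();
    out[x * stride] = g[dq.front() * stride];
  }
}

enum Op { ERODE, DILATE };

static NumericMatrix apply_line(const NumericMatrix &img, int k, bool horizontal, Op op) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  if (horizontal) { // along the column index: each image row, stride = nr
    for (int r = 0; r < nr; ++r) {
      if (op == ERODE) erode_vec(&img[0] + r, &out[0] + r, nc, k, nr);
      else dilate_vec(&img[0] + r, &out[0] + r, nc, k, nr);
    }
  } else { // along the row index: each image column, contiguous
    for (int c = 0; c < nc; ++c) {
      if (op == ERODE) erode_vec(&img[0] + (R_xlen_t)c * nr, &out[0] + (R_xlen_t)c * nr, nr, k, 1);
      else dilate_vec(&img[0] + (R_xlen_t)c * nr, &out[0] + (R_xlen_t)c * nr, nr, k, 1);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_erode_line(NumericMatrix img, int k, bool horizontal) {
  return apply_line(img, k, horizontal, ERODE);
}

// [[Rcpp::export]]
NumericMatrix cpp_dilate_line(NumericMatrix img, int k, bool horizontal) {
  return apply_line(img, k, horizontal, DILATE);
}

// [[Rcpp::export]]
NumericMatrix cpp_open_line(NumericMatrix img, int k, bool horizontal) {
  return apply_line(apply_line(img, k, horizontal, ERODE), k, horizontal, DILATE);
}

// opening by a k x k square SE, separable into horizontal and vertical passes
// [[Rcpp::export]]
NumericMatrix cpp_open_square(NumericMatrix img, int k) {
  NumericMatrix e = apply_line(apply_line(img, k, true, ERODE), k, false, ERODE);
  return apply_line(apply_line(e, k, false, DILATE), k, true, DILATE);
}
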