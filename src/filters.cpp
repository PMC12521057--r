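#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Local sample standard deviation over a square sliding window.
// Two-pass per window (mean, then sum of squared deviations) so the result
// agrees with a direct sd() recomputation to floating-point roundoff.
// Pixels whose window exits the slice get NA (no padding).
// [[Rcpp::export]]
NumericMatrix local_sd_cpp(const NumericMatrix& x, const int window) {
  const int nr = x.nrow(), nc = x.ncol();
  const int h = window / 2;           // window is odd, checked in R
  const int n = window * window;
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  if (nr < window || nc < window) return out;
  for (int j = h; j < nc - h; ++j) {
    for (int i = h; i < nr - h; ++i) {
      double s = 0.0;
      for (int jj = j - h; jj <= j + h; ++jj)
        for (int ii = i - h; ii <= i + h; ++ii)
          s += x(ii, jj);
      const double mean = s / n;
      double ss = 0.0;
      for (int jj = j - h; jj <= j + h; ++jj)
        for (int ii = i - h; ii <= i + h; ++ii) {
          const double d = x(ii, jj) - mean;
          ss += d * d;
        }
      out(i, j) = std::sqrt(ss / (n - 1));
    }
  }
  return out;
}

// Exact 2-D median filter with replicate (nearest-pixel) borders.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(const NumericMatrix& x, const int kernel) {
  const int nr = x.nrow(), nc = x.ncol();
  const int h = kernel / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(kernel * kernel);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int jj = j - h; jj <= j + h; ++jj) {
        const int jc = std::min(std::max(jj, 0), nc - 1);
        for (int ii = i - h; ii <= i + h; ++ii) {
          const int ic = std::min(std::max(ii, 0), nr - 1);
          buf.push_back(x(ic, jc));
        }
      }
      const size_t mid = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(i, j) = buf[mid];
    }
  }
  return out;
}

// Per-ROI sample SD over a fixed grid of square ROIs; an ROI contributes only
// if the mask is TRUE on every one of its pixels. Returns one value per ROI
// origin, NA where the ROI is not fully inside the mask.
// [[Rcpp::export]]
NumericVector roi_sd_cpp(const NumericMatrix& x, const LogicalMatrix& mask,
                         const IntegerVector& row0, const IntegerVector& col0,
                         const int roi) {
  const int ng = row0.size();
  const int n = roi * roi;
  NumericVector out(ng, NA_REAL);
  for (int g = 0; g < ng; ++g) {
    const int r0 = row0[g] - 1, c0 = col0[g] - 1;  // 1-based origins from R
    bool inside = true;
    for (int jj = c0; jj < c0 + roi && inside; ++jj)
      for (int ii = r0; ii < r0 + roi; ++ii)
        if (!mask(ii, jj)) { inside = false; break; }
    if (!inside) continue;
    double s = 0.0;
    for (int jj = c0; jj < c0 + roi; ++jj)
      for (int ii = r0; ii < r0 + roi; ++ii)
        s += x(ii, jj);
    const double mean = s / n;
    double ss = 0.0;
    for (int jj = c0; jj < c0 + roi; ++jj)
      for (int ii = r0; ii < r0 + roi; ++ii) {
        const double d = x(ii, jj) - mean;
        ss += d * d;
      }
    out[g] = std::sqrt(ss / (n - 1));
  }
  return out;
}
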