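#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of buf[0..n) with R's convention (mean of the two middle order
// statistics for even n); buf is clobbered
static double median_inplace(std::vector<double>& buf) {
  const size_t n = buf.size();
  if (n == 0) return NA_REAL;
  const size_t h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.end());
  double med = buf[h];
  if (n % 2 == 0) {
    const double lo = *std::max_element(buf.begin(), buf.begin() + h);
    med = (med + lo) / 2.0;
  }
  return med;
}

// Per-group column medians. g holds 1-based group ids; NAs are dropped
// per (group, column).
// [[Rcpp::export]]
NumericMatrix grouped_col_medians_cpp(NumericMatrix x, IntegerVector g,
                                      int ngroups) {
  const int n = x.nrow(), m = x.ncol();
  if (g.size() != n) stop("group vector length mismatch");
  std::vector<std::vector<int> > rows(ngroups);
  for (int i = 0; i < n; ++i) {
    const int k = g[i];
    if (k < 1 || k > ngroups) stop("group id out of range");
    rows[k - 1].push_back(i);
  }
  NumericMatrix out(ngroups, m);
  std::vector<double> buf;
  for (int j = 0; j < m; ++j) {
    const double* col = &x(0, j);
    for (int k = 0; k < ngroups; ++k) {
      const std::vector<int>& r = rows[k];
      buf.clear();
      buf.reserve(r.size());
      for (size_t q = 0; q < r.size(); ++q) {
        const double v = col[r[q]];
        if (!ISNAN(v)) buf.push_back(v);
      }
      out(k, j) = median_inplace(buf);
    }
  }
  return out;
}

// Per-group column medians of |x - center|, center per (group, column):
// the unscaled MAD used for control-based normalization.
// [[Rcpp::export]]
NumericMatrix grouped_col_mads_cpp(NumericMatrix x, IntegerVector g,
                                   int ngroups, NumericMatrix center) {
  const int n = x.nrow(), m = x.ncol();
  if (g.size() != n) stop("group vector length mismatch");
  if (center.nrow() != ngroups || center.ncol() != m)
    stop("center dimension mismatch");
  std::vector<std::vector<int> > rows(ngroups);
  for (int i = 0; i < n; ++i) rows[g[i] - 1].push_back(i);
  NumericMatrix out(ngroups, m);
  std::vector<double> buf;
  for (int j = 0; j < m; ++j) {
    const double* col = &x(0, j);
    for (int k = 0; k < ngroups; ++k) {
      const std::vector<int>& r = rows[k];
      const double c = center(k, j);
      buf.clear();
      buf.reserve(r.size());
      for (size_t q = 0; q < r.size(); ++q) {
        const double v = col[r[q]];
        if (!ISNAN(v)) buf.push_back(std::abs(v - c));
      }
      out(k, j) = median_inplace(buf);
    }
  }
  return out;
}

// Fused per-group location/scale transform: (x - center[g, j]) / scale[g, j].
// [[Rcpp::export]]
NumericMatrix scale_by_group_cpp(NumericMatrix x, IntegerVector g,
                                 NumericMatrix center, NumericMatrix scale) {
  const int n = x.nrow(), m = x.ncol();
  if (g.size() != n) stop("group vector length mismatch");
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const double* col = &x(0, j);
    double* o = &out(0, j);
    for (int i = 0; i < n; ++i) {
      const int k = g[i] - 1;
      o[i] = (col[i] - center(k, j)) / scale(k, j);
    }
  }
  return out;
}
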