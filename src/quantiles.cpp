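#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// type-7 quantile of buf[0..n-1] (modifies buf)
static double q7(std::vector<double>& buf, double p) {
  const int n = (int)buf.size();
  if (n == 1) return buf[0];
  const double h = (n - 1) * p;
  const int lo = (int)std::floor(h);
  const int hi = lo < n - 1 ? lo + 1 : lo;
  std::nth_element(buf.begin(), buf.begin() + lo, buf.end());
  const double xlo = buf[lo];
  if (hi == lo) return xlo;
  const double xhi = *std::min_element(buf.begin() + lo + 1, buf.end());
  return xlo + (h - lo) * (xhi - xlo);
}

// Day-of-year windowed percentile: x is ncell x (365*nyear); for each cell
// and each day d, the threshold is the p-quantile of all values whose day of
// year falls in the window [d-hw, d+hw] (wrapping across the year boundary),
// pooled over all years.  Returns ncell x 365.
// [[Rcpp::export(name = ".cpp_doy_quantile")]]
NumericMatrix cpp_doy_quantile(const NumericMatrix& x, double p, int window) {
  const int ncell = x.nrow(), ntime = x.ncol();
  if (ntime % 365 != 0) stop("series length must be a multiple of 365");
  if (window < 1 || window % 2 == 0) stop("window must be odd and positive");
  const int nyear = ntime / 365, hw = window / 2;
  NumericMatrix out(ncell, 365);
  // per-cell day-of-year-major layout, padded by hw days at both ends so a
  // wrapped window is a contiguous slice (cache-friendly: the source matrix
  // is cell-major and row access strides across columns)
  const int ndoy = 365 + 2 * hw;
  std::vector<double> row(ntime), dm((size_t)ndoy * nyear),
      buf((size_t)window * nyear);
  for (int i = 0; i < ncell; ++i) {
    for (int t = 0; t < ntime; ++t) row[t] = x(i, t);
    for (int d = 0; d < ndoy; ++d) {
      int doy = (d - hw + 365) % 365;
      for (int y = 0; y < nyear; ++y)
        dm[(size_t)d * nyear + y] = row[y * 365 + doy];
    }
    for (int d = 0; d < 365; ++d) {
      std::copy(dm.begin() + (size_t)d * nyear,
                dm.begin() + (size_t)(d + window) * nyear, buf.begin());
      out(i, d) = q7(buf, p);
    }
  }
  return out;
}

// Row-wise type-7 quantile of a matrix.
// [[Rcpp::export(name = ".cpp_row_quantile")]]
NumericVector cpp_row_quantile(const NumericMatrix& x, double p) {
  const int n = x.nrow(), m = x.ncol();
  NumericVector out(n);
  std::vector<double> buf(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) buf[j] = x(i, j);
    out[i] = q7(buf, p);
  }
  return out;
}
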