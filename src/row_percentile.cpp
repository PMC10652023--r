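#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Row-wise percentile of a pixels-by-observations matrix with NA handling.
// interpolate = true reproduces the linear order-statistic interpolation of
// stats::quantile(type = 7); false gives the nearest-rank (ceil) statistic.
// [[Rcpp::export]]
List cpp_row_percentile(NumericMatrix x, double p, bool interpolate) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nr);
  IntegerVector nvalid(nr);
  std::vector<double> buf;
  buf.reserve(nc);
  for (int i = 0; i < nr; ++i) {
    buf.clear();
    for (int j = 0; j < nc; ++j) {
      double v = x(i, j);
      if (!NumericVector::is_na(v)) buf.push_back(v);
    }
    const int n = (int) buf.size();
    nvalid[i] = n;
    if (n == 0) { out[i] = NA_REAL; continue; }
    std::sort(buf.begin(), buf.end());
    if (interpolate) {
      double h = (n - 1) * p / 100.0;
      int lo = (int) std::floor(h);
      int hi = lo + 1;
      if (hi >= n) { out[i] = buf[n - 1]; }
      else out[i] = buf[lo] + (h - lo) * (buf[hi] - buf[lo]);
    } else {
      int k = (int) std::ceil(n * p / 100.0);
      if (k < 1) k = 1;
      if (k > n) k = n;
      out[i] = buf[k - 1];
    }
  }
  return List::create(_["value"] = out, _["n_valid"] = nvalid);
}
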