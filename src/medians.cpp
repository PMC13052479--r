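#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Row-wise medians of an n x k matrix (k = frames in a temporal batch).
// [[Rcpp::export]]
NumericVector cpp_row_medians(NumericMatrix x) {
  const int n = x.nrow(), k = x.ncol();
  NumericVector out(n);
  std::vector<double> buf(k);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) buf[j] = x(i, j);
    int h = k / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (k % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      m = (m + lo) / 2.0;
    }
    out[i] = m;
  }
  return out;
}
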