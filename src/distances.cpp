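#include <Rcpp.h>
using namespace Rcpp;

// Squared Euclidean distance from x to every column of W.
// W is input_dim x n_nodes; the hot loop of BMU search.
// [[Rcpp::export(name = ".colDist2")]]
NumericVector colDist2(NumericMatrix W, NumericVector x) {
  const int d = W.nrow(), n = W.ncol();
  if (x.size() != d) stop("dimension mismatch: %d vs %d", (int)x.size(), d);
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    const double *wj = &W(0, j);
    double s = 0.0;
    for (int i = 0; i < d; ++i) {
      const double diff = wj[i] - x[i];
      s += diff * diff;
    }
    out[j] = s;
  }
  return out;
}
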