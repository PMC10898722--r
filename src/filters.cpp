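#include <Rcpp.h>
using namespace Rcpp;

// Peak-to-peak amplitude (max over rows of row-max minus row-min) for each
// slice of a channels x samples x trials array.
// [[Rcpp::export(name = ".ptp_by_trial")]]
NumericVector ptp_by_trial(NumericVector arr, IntegerVector dims) {
  int nc = dims[0], ns = dims[1], nt = dims[2];
  NumericVector out(nt);
  const double *p = REAL(arr);
  std::vector<double> mx(nc), mn(nc);
  for (int t = 0; t < nt; ++t) {
    const double *pt = p + (size_t)t * nc * ns;
    for (int c = 0; c < nc; ++c) { mx[c] = -INFINITY; mn[c] = INFINITY; }
    for (int s = 0; s < ns; ++s) {
      const double *col = pt + (size_t)s * nc;
      for (int c = 0; c < nc; ++c) {
        double v = col[c];
        if (v > mx[c]) mx[c] = v;
        if (v < mn[c]) mn[c] = v;
      }
    }
    double best = 0.0;
    for (int c = 0; c < nc; ++c)
      if (mx[c] - mn[c] > best) best = mx[c] - mn[c];
    out[t] = best;
  }
  return out;
}

// Subtract the per-column (per-sample) mean across rows, in place.
// [[Rcpp::export(name = ".subtract_colmeans_inplace")]]
void subtract_colmeans_inplace(NumericMatrix x) {
  int nc = x.nrow(), n = x.ncol();
  double *p = REAL(x);
  for (int j = 0; j < n; ++j) {
    double *col = p + (size_t)j * nc;
    double m = 0;
    for (int c = 0; c < nc; ++c) m += col[c];
    m /= nc;
    for (int c = 0; c < nc; ++c) col[c] -= m;
  }
}
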