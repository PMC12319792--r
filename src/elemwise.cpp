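// Elementwise training helpers kept out of R to avoid large temporaries.
#include <Rcpp.h>

using namespace Rcpp;

// leaky rectifier, slope 0.1
// [[Rcpp::export]]
NumericVector cpp_leaky(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = x[i] > 0 ? x[i] : 0.1 * x[i];
  return out;
}

// gradient through the leaky rectifier given the post-activation values
// [[Rcpp::export]]
NumericVector cpp_leaky_grad(NumericVector act, NumericVector g) {
  NumericVector out(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i)
    out[i] = act[i] > 0 ? g[i] : 0.1 * g[i];
  return out;
}

// mat + bias recycled over rows
// [[Rcpp::export]]
NumericMatrix cpp_add_bias(NumericMatrix m, NumericVector b) {
  int n = m.nrow(), c = m.ncol();
  NumericMatrix out(n, c);
  for (int k = 0; k < c; ++k) {
    double bk = b[k];
    const double *src = m.begin() + (R_xlen_t)k * n;
    double *dst = out.begin() + (R_xlen_t)k * n;
    for (int i = 0; i < n; ++i) dst[i] = src[i] + bk;
  }
  return out;
}
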