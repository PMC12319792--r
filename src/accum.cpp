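// Scatter-add of matrix rows into bins: the workhorse behind graph
// neighborhood aggregation and per-vertex accumulation of face/edge terms.
#include <Rcpp.h>

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_index_accum(IntegerVector idx, NumericMatrix vals, int n) {
  int m = vals.nrow(), c = vals.ncol();
  NumericMatrix out(n, c);
  double *o = out.begin();
  const double *v = vals.begin();
  for (int k = 0; k < c; ++k) {
    const double *vk = v + (R_xlen_t)k * m;
    double *ok = o + (R_xlen_t)k * n;
    for (int i = 0; i < m; ++i) ok[idx[i] - 1] += vk[i];
  }
  return out;
}

// out[dst[i], ] += vals[src[i], ] — fused gather/scatter for graph
// neighborhood aggregation without materializing the gathered rows
// [[Rcpp::export]]
NumericMatrix cpp_gather_accum(IntegerVector src, IntegerVector dst,
                               NumericMatrix vals, int n) {
  int m = src.size(), c = vals.ncol(), vr = vals.nrow();
  NumericMatrix out(n, c);
  double *o = out.begin();
  const double *v = vals.begin();
  for (int k = 0; k < c; ++k) {
    const double *vk = v + (R_xlen_t)k * vr;
    double *ok = o + (R_xlen_t)k * n;
    for (int i = 0; i < m; ++i) ok[dst[i] - 1] += vk[src[i] - 1];
  }
  return out;
}
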