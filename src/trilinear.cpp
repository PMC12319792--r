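// Trilinear interpolation of multi-channel volumes at continuous voxel
// coordinates (0-based, voxel centers at integers), with the adjoint
// scatter operation used during training.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline void corner_setup(double p, int n, int &i0, int &i1, double &f) {
  if (p < 0.0) p = 0.0;
  if (p > n - 1.0) p = n - 1.0;
  i0 = (int)std::floor(p);
  if (i0 > n - 2) i0 = n - 2;
  if (i0 < 0) i0 = 0;
  i1 = i0 + 1;
  f = p - i0;
  if (n == 1) { i0 = i1 = 0; f = 0.0; }
}

// vol: array dim (H, W, D, C); points: n x 3 voxel coords -> n x C
// [[Rcpp::export]]
NumericMatrix cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix points) {
  int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  int n = points.nrow();
  NumericMatrix out(n, C);
  R_xlen_t sW = H, sD = (R_xlen_t)H * W, sC = (R_xlen_t)H * W * D;
  for (int i = 0; i < n; ++i) {
    int x0, x1, y0, y1, z0, z1;
    double fx, fy, fz;
    corner_setup(points(i, 0), H, x0, x1, fx);
    corner_setup(points(i, 1), W, y0, y1, fy);
    corner_setup(points(i, 2), D, z0, z1, fz);
    double w000 = (1 - fx) * (1 - fy) * (1 - fz), w100 = fx * (1 - fy) * (1 - fz);
    double w010 = (1 - fx) * fy * (1 - fz), w110 = fx * fy * (1 - fz);
    double w001 = (1 - fx) * (1 - fy) * fz, w101 = fx * (1 - fy) * fz;
    double w011 = (1 - fx) * fy * fz, w111 = fx * fy * fz;
    for (int c = 0; c < C; ++c) {
      R_xlen_t b = sC * c;
      out(i, c) =
          w000 * vol[b + x0 + sW * y0 + sD * z0] + w100 * vol[b + x1 + sW * y0 + sD * z0] +
          w010 * vol[b + x0 + sW * y1 + sD * z0] + w110 * vol[b + x1 + sW * y1 + sD * z0] +
          w001 * vol[b + x0 + sW * y0 + sD * z1] + w101 * vol[b + x1 + sW * y0 + sD * z1] +
          w011 * vol[b + x0 + sW * y1 + sD * z1] + w111 * vol[b + x1 + sW * y1 + sD * z1];
    }
  }
  return out;
}

// adjoint: scatter grad_out (n x C) back onto a zero volume of dim dims
// [[Rcpp::export]]
NumericVector cpp_trilinear_adjoint(IntegerVector dims, NumericMatrix points,
                                    NumericMatrix grad_out) {
  int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  int n = points.nrow();
  NumericVector grad((R_xlen_t)H * W * D * C);
  R_xlen_t sW = H, sD = (R_xlen_t)H * W, sC = (R_xlen_t)H * W * D;
  for (int i = 0; i < n; ++i) {
    int x0, x1, y0, y1, z0, z1;
    double fx, fy, fz;
    corner_setup(points(i, 0), H, x0, x1, fx);
    corner_setup(points(i, 1), W, y0, y1, fy);
    corner_setup(points(i, 2), D, z0, z1, fz);
    double w000 = (1 - fx) * (1 - fy) * (1 - fz), w100 = fx * (1 - fy) * (1 - fz);
    double w010 = (1 - fx) * fy * (1 - fz), w110 = fx * fy * (1 - fz);
    double w001 = (1 - fx) * (1 - fy) * fz, w101 = fx * (1 - fy) * fz;
    double w011 = (1 - fx) * fy * fz, w111 = fx * fy * fz;
    for (int c = 0; c < C; ++c) {
      double g = grad_out(i, c);
      if (g == 0.0) continue;
      R_xlen_t b = sC * c;
      grad[b + x0 + sW * y0 + sD * z0] += w000 * g;
      grad[b + x1 + sW * y0 + sD * z0] += w100 * g;
      grad[b + x0 + sW * y1 + sD * z0] += w010 * g;
      grad[b + x1 + sW * y1 + sD * z0] += w110 * g;
      grad[b + x0 + sW * y0 + sD * z1] += w001 * g;
      grad[b + x1 + sW * y0 + sD * z1] += w101 * g;
      grad[b + x0 + sW * y1 + sD * z1] += w011 * g;
      grad[b + x1 + sW * y1 + sD * z1] += w111 * g;
    }
  }
  return grad;
}
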