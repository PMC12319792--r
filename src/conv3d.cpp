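// Minimal 3D convolution kernels (3x3x3, zero padding 1, stride 1 or 2)
// with hand-written adjoints, plus nearest-neighbour upsampling. These back
// the small encoder-decoder that extracts image features for the mesh flow.
#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static inline int out_dim(int n, int stride) { return (n + stride - 1) / stride; }

// input (H,W,D,Cin), weights (3,3,3,Cin,Cout), bias (Cout)
// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector input, IntegerVector dims,
                             NumericVector weights, NumericVector bias,
                             int cout, int stride) {
  int H = dims[0], W = dims[1], D = dims[2], Cin = dims[3];
  int Ho = out_dim(H, stride), Wo = out_dim(W, stride), Do = out_dim(D, stride);
  NumericVector out((R_xlen_t)Ho * Wo * Do * cout);
  R_xlen_t isW = H, isD = (R_xlen_t)H * W, isC = (R_xlen_t)H * W * D;
  R_xlen_t osW = Ho, osD = (R_xlen_t)Ho * Wo, osC = (R_xlen_t)Ho * Wo * Do;
  const double *in = input.begin(), *w = weights.begin();
  double *o = out.begin();
  for (int co = 0; co < cout; ++co) {
    double b = bias[co];
    for (int zo = 0; zo < Do; ++zo)
      for (int yo = 0; yo < Wo; ++yo)
        for (int xo = 0; xo < Ho; ++xo) {
          double acc = b;
          int xi0 = xo * stride - 1, yi0 = yo * stride - 1, zi0 = zo * stride - 1;
          for (int kz = 0; kz < 3; ++kz) {
            int zi = zi0 + kz;
            if (zi < 0 || zi >= D) continue;
            for (int ky = 0; ky < 3; ++ky) {
              int yi = yi0 + ky;
              if (yi < 0 || yi >= W) continue;
              for (int kx = 0; kx < 3; ++kx) {
                int xi = xi0 + kx;
                if (xi < 0 || xi >= H) continue;
                R_xlen_t ibase = xi + isW * yi + isD * zi;
                R_xlen_t wbase = kx + 3 * (ky + 3 * kz);
                for (int ci = 0; ci < Cin; ++ci)
                  acc += in[ibase + isC * ci] * w[wbase + 27 * (ci + (R_xlen_t)Cin * co)];
              }
            }
          }
          o[xo + osW * yo + osD * zo + osC * co] = acc;
        }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector input, IntegerVector dims,
                    NumericVector weights, int cout, int stride,
                    NumericVector grad_out) {
  int H = dims[0], W = dims[1], D = dims[2], Cin = dims[3];
  int Ho = out_dim(H, stride), Wo = out_dim(W, stride), Do = out_dim(D, stride);
  NumericVector gin((R_xlen_t)H * W * D * Cin);
  NumericVector gw(weights.size());
  NumericVector gb(cout);
  R_xlen_t isW = H, isD = (R_xlen_t)H * W, isC = (R_xlen_t)H * W * D;
  R_xlen_t osW = Ho, osD = (R_xlen_t)Ho * Wo, osC = (R_xlen_t)Ho * Wo * Do;
  const double *in = input.begin(), *w = weights.begin(), *go = grad_out.begin();
  double *gi = gin.begin(), *gww = gw.begin();
  for (int co = 0; co < cout; ++co) {
    double gbacc = 0.0;
    for (int zo = 0; zo < Do; ++zo)
      for (int yo = 0; yo < Wo; ++yo)
        for (int xo = 0; xo < Ho; ++xo) {
          double g = go[xo + osW * yo + osD * zo + osC * co];
          if (g == 0.0) continue;
          gbacc += g;
          int xi0 = xo * stride - 1, yi0 = yo * stride - 1, zi0 = zo * stride - 1;
          for (int kz = 0; kz < 3; ++kz) {
            int zi = zi0 + kz;
            if (zi < 0 || zi >= D) continue;
            for (int ky = 0; ky < 3; ++ky) {
              int yi = yi0 + ky;
              if (yi < 0 || yi >= W) continue;
              for (int kx = 0; kx < 3; ++kx) {
                int xi = xi0 + kx;
                if (xi < 0 || xi >= H) continue;
                R_xlen_t ibase = xi + isW * yi + isD * zi;
                R_xlen_t wbase = kx + 3 * (ky + 3 * kz);
                for (int ci = 0; ci < Cin; ++ci) {
                  R_xlen_t wi = wbase + 27 * (ci + (R_xlen_t)Cin * co);
                  gi[ibase + isC * ci] += g * w[wi];
                  gww[wi] += g * in[ibase + isC * ci];
                }
              }
            }
          }
        }
    gb[co] = gbacc;
  }
  return List::create(_["grad_input"] = gin, _["grad_weights"] = gw,
                      _["grad_bias"] = gb);
}

// nearest-neighbour upsample from (h,w,d,C) to (H,W,D,C), factor-2 grids
// [[Rcpp::export]]
NumericVector cpp_upsample_nearest(NumericVector input, IntegerVector dims_in,
                                   IntegerVector dims_out) {
  int h = dims_in[0], w = dims_in[1], d = dims_in[2], C = dims_in[3];
  int H = dims_out[0], W = dims_out[1], D = dims_out[2];
  NumericVector out((R_xlen_t)H * W * D * C);
  R_xlen_t isW = h, isD = (R_xlen_t)h * w, isC = (R_xlen_t)h * w * d;
  R_xlen_t osW = H, osD = (R_xlen_t)H * W, osC = (R_xlen_t)H * W * D;
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < D; ++z) {
      int zi = z / 2; if (zi >= d) zi = d - 1;
      for (int y = 0; y < W; ++y) {
        int yi = y / 2; if (yi >= w) yi = w - 1;
        for (int x = 0; x < H; ++x) {
          int xi = x / 2; if (xi >= h) xi = h - 1;
          out[x + osW * y + osD * z + osC * c] =
              input[xi + isW * yi + isD * zi + isC * c];
        }
      }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nearest_adjoint(NumericVector grad_out,
                                           IntegerVector dims_in,
                                           IntegerVector dims_out) {
  int h = dims_in[0], w = dims_in[1], d = dims_in[2], C = dims_in[3];
  int H = dims_out[0], W = dims_out[1], D = dims_out[2];
  NumericVector gin((R_xlen_t)h * w * d * C);
  R_xlen_t isW = h, isD = (R_xlen_t)h * w, isC = (R_xlen_t)h * w * d;
  R_xlen_t osW = H, osD = (R_xlen_t)H * W, osC = (R_xlen_t)H * W * D;
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < D; ++z) {
      int zi = z / 2; if (zi >= d) zi = d - 1;
      for (int y = 0; y < W; ++y) {
        int yi = y / 2; if (yi >= w) yi = w - 1;
        for (int x = 0; x < H; ++x) {
          int xi = x / 2; if (xi >= h) xi = h - 1;
          gin[xi + isW * yi + isD * zi + isC * c] +=
              grad_out[x + osW * y + osD * z + osC * c];
        }
      }
    }
  return gin;
}
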