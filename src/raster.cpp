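// Voxelization of a closed triangle mesh by scanline parity counting.
// Vertices are expected in continuous voxel coordinates (0-based indices,
// voxel centers at integers); rays run along the first array dimension.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_rasterize_parity(NumericMatrix vertices, IntegerMatrix faces0,
                                   int H, int W, int D) {
  // jitter rays off lattice-aligned mesh edges (measure-zero event otherwise)
  const double ey = 3.1e-4, ez = 2.3e-4;
  std::vector<std::vector<double>> rows((size_t)W * D);
  int nf = faces0.nrow();
  for (int t = 0; t < nf; ++t) {
    double x0 = vertices(faces0(t, 0), 0), y0 = vertices(faces0(t, 0), 1), z0 = vertices(faces0(t, 0), 2);
    double x1 = vertices(faces0(t, 1), 0), y1 = vertices(faces0(t, 1), 1), z1 = vertices(faces0(t, 1), 2);
    double x2 = vertices(faces0(t, 2), 0), y2 = vertices(faces0(t, 2), 1), z2 = vertices(faces0(t, 2), 2);
    double det = (y1 - y0) * (z2 - z0) - (z1 - z0) * (y2 - y0);
    if (std::fabs(det) < 1e-14) continue;  // parallel to ray; neighbours cover it
    int ylo = std::max(0, (int)std::ceil(std::min(y0, std::min(y1, y2)) - ey));
    int yhi = std::min(W - 1, (int)std::floor(std::max(y0, std::max(y1, y2)) - ey + 1));
    int zlo = std::max(0, (int)std::ceil(std::min(z0, std::min(z1, z2)) - ez));
    int zhi = std::min(D - 1, (int)std::floor(std::max(z0, std::max(z1, z2)) - ez + 1));
    for (int z = zlo; z <= zhi; ++z) {
      double zq = z + ez;
      for (int y = ylo; y <= yhi; ++y) {
        double yq = y + ey;
        double b1 = ((yq - y0) * (z2 - z0) - (zq - z0) * (y2 - y0)) / det;
        double b2 = ((y1 - y0) * (zq - z0) - (z1 - z0) * (yq - y0)) / det;
        double b0 = 1.0 - b1 - b2;
        if (b0 < 0.0 || b1 < 0.0 || b2 < 0.0) continue;
        double xc = b0 * x0 + b1 * x1 + b2 * x2;
        rows[(size_t)y + (size_t)W * z].push_back(xc);
      }
    }
  }
  IntegerVector out((R_xlen_t)H * W * D);
  for (int z = 0; z < D; ++z)
    for (int y = 0; y < W; ++y) {
      std::vector<double> &xs = rows[(size_t)y + (size_t)W * z];
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      size_t k = 0;
      for (int x = 0; x < H; ++x) {
        while (k < xs.size() && xs[k] < (double)x) ++k;
        if (k & 1) out[(R_xlen_t)x + (R_xlen_t)H * (y + (R_xlen_t)W * z)] = 1;
      }
    }
  return out;
}
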