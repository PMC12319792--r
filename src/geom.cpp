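// Mesh geometry kernels: exact point-to-triangle distance (BVH accelerated),
// triangle-triangle self-intersection tests, and kd-tree nearest neighbours.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator-(const Vec3 &o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3 &o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3 &o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3 &o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm2() const { return x * x + y * y + z * z; }
};

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection).
static Vec3 closest_point_triangle(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                                   const Vec3 &c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = ab.dot(ap), d2 = ac.dot(ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = ab.dot(bp), d4 = ac.dot(bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  Vec3 cp = p - c;
  double d5 = ab.dot(cp), d6 = ac.dot(cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

struct BVHNode {
  double bmin[3], bmax[3];
  int left, right;   // children, or -1 for leaf
  int start, count;  // leaf triangle range into order[]
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;
  const NumericMatrix *V;
  const IntegerMatrix *F;

  void tri_bounds(int t, double *bmin, double *bmax) const {
    const NumericMatrix &v = *V;
    const IntegerMatrix &f = *F;
    for (int k = 0; k < 3; ++k) {
      double a = v(f(t, 0), k), b = v(f(t, 1), k), c = v(f(t, 2), k);
      bmin[k] = std::min(a, std::min(b, c));
      bmax[k] = std::max(a, std::max(b, c));
    }
  }

  int build(int start, int count) {
    BVHNode node;
    node.bmin[0] = node.bmin[1] = node.bmin[2] = std::numeric_limits<double>::infinity();
    node.bmax[0] = node.bmax[1] = node.bmax[2] = -std::numeric_limits<double>::infinity();
    for (int i = start; i < start + count; ++i) {
      double tmin[3], tmax[3];
      tri_bounds(order[i], tmin, tmax);
      for (int k = 0; k < 3; ++k) {
        node.bmin[k] = std::min(node.bmin[k], tmin[k]);
        node.bmax[k] = std::max(node.bmax[k], tmax[k]);
      }
    }
    if (count <= 8) {
      node.left = node.right = -1;
      node.start = start;
      node.count = count;
      nodes.push_back(node);
      return (int)nodes.size() - 1;
    }
    int axis = 0;
    double ext = node.bmax[0] - node.bmin[0];
    for (int k = 1; k < 3; ++k)
      if (node.bmax[k] - node.bmin[k] > ext) { ext = node.bmax[k] - node.bmin[k]; axis = k; }
    const NumericMatrix &v = *V;
    const IntegerMatrix &f = *F;
    std::nth_element(order.begin() + start, order.begin() + start + count / 2,
                     order.begin() + start + count,
                     [&](int a, int b) {
                       double ca = v(f(a, 0), axis) + v(f(a, 1), axis) + v(f(a, 2), axis);
                       double cb = v(f(b, 0), axis) + v(f(b, 1), axis) + v(f(b, 2), axis);
                       return ca < cb;
                     });
    int mid = count / 2;
    int self = (int)nodes.size();
    nodes.push_back(node);  // placeholder
    int l = build(start, mid);
    int r = build(start + mid, count - mid);
    nodes[self].left = l;
    nodes[self].right = r;
    nodes[self].start = -1;
    nodes[self].count = 0;
    return self;
  }

  static double box_dist2(const BVHNode &n, const Vec3 &p) {
    double d2 = 0.0;
    double c[3] = {p.x, p.y, p.z};
    for (int k = 0; k < 3; ++k) {
      double d = 0.0;
      if (c[k] < n.bmin[k]) d = n.bmin[k] - c[k];
      else if (c[k] > n.bmax[k]) d = c[k] - n.bmax[k];
      d2 += d * d;
    }
    return d2;
  }

  void query(const Vec3 &p, double &best2, Vec3 &bestpt, int node_idx) const {
    const BVHNode &n = nodes[node_idx];
    if (box_dist2(n, p) >= best2) return;
    if (n.left < 0) {
      const NumericMatrix &v = *V;
      const IntegerMatrix &f = *F;
      for (int i = n.start; i < n.start + n.count; ++i) {
        int t = order[i];
        Vec3 a(v(f(t, 0), 0), v(f(t, 0), 1), v(f(t, 0), 2));
        Vec3 b(v(f(t, 1), 0), v(f(t, 1), 1), v(f(t, 1), 2));
        Vec3 c(v(f(t, 2), 0), v(f(t, 2), 1), v(f(t, 2), 2));
        Vec3 q = closest_point_triangle(p, a, b, c);
        double d2 = (p - q).norm2();
        if (d2 < best2) { best2 = d2; bestpt = q; }
      }
      return;
    }
    double dl = box_dist2(nodes[n.left], p), dr = box_dist2(nodes[n.right], p);
    if (dl < dr) { query(p, best2, bestpt, n.left); query(p, best2, bestpt, n.right); }
    else { query(p, best2, bestpt, n.right); query(p, best2, bestpt, n.left); }
  }
};

// [[Rcpp::export]]
List cpp_point_mesh_distance(NumericMatrix points, NumericMatrix vertices,
                             IntegerMatrix faces0, bool return_closest = false) {
  int n = points.nrow(), nf = faces0.nrow();
  NumericVector out(n);
  NumericMatrix closest;
  if (return_closest) closest = NumericMatrix(n, 3);
  BVH bvh;
  bvh.V = &vertices;
  bvh.F = &faces0;
  bvh.order.resize(nf);
  for (int i = 0; i < nf; ++i) bvh.order[i] = i;
  bvh.build(0, nf);
  for (int i = 0; i < n; ++i) {
    Vec3 p(points(i, 0), points(i, 1), points(i, 2));
    double best2 = std::numeric_limits<double>::infinity();
    Vec3 bestpt;
    bvh.query(p, best2, bestpt, 0);
    out[i] = std::sqrt(best2);
    if (return_closest) {
      closest(i, 0) = bestpt.x; closest(i, 1) = bestpt.y; closest(i, 2) = bestpt.z;
    }
  }
  if (return_closest) return List::create(_["distance"] = out, _["closest"] = closest);
  return List::create(_["distance"] = out);
}

// ---- triangle-triangle intersection (Moller 1997 interval test) ----

static bool coplanar_tri_tri(const Vec3 &n, const Vec3 &v0, const Vec3 &v1,
                             const Vec3 &v2, const Vec3 &u0, const Vec3 &u1,
                             const Vec3 &u2);

static inline bool edge_edge_test(double ax, double ay, const double *v0,
                                  const double *u0, const double *u1) {
  double bx = u0[0] - u1[0], by = u0[1] - u1[1];
  double cx = v0[0] - u0[0], cy = v0[1] - u0[1];
  double f = ay * bx - ax * by;
  double d = by * cx - bx * cy;
  if ((f > 0 && d >= 0 && d <= f) || (f < 0 && d <= 0 && d >= f)) {
    double e = ax * cy - ay * cx;
    if (f > 0) { if (e >= 0 && e <= f) return true; }
    else { if (e <= 0 && e >= f) return true; }
  }
  return false;
}

static bool edge_against_tri(const double *v0, const double *v1, const double *u0,
                             const double *u1, const double *u2) {
  double ax = v1[0] - v0[0], ay = v1[1] - v0[1];
  if (edge_edge_test(ax, ay, v0, u0, u1)) return true;
  if (edge_edge_test(ax, ay, v0, u1, u2)) return true;
  if (edge_edge_test(ax, ay, v0, u2, u0)) return true;
  return false;
}

static bool point_in_tri_2d(const double *p, const double *a, const double *b,
                            const double *c) {
  double d1 = (b[0] - a[0]) * (p[1] - a[1]) - (b[1] - a[1]) * (p[0] - a[0]);
  double d2 = (c[0] - b[0]) * (p[1] - b[1]) - (c[1] - b[1]) * (p[0] - b[0]);
  double d3 = (a[0] - c[0]) * (p[1] - c[1]) - (a[1] - c[1]) * (p[0] - c[0]);
  bool has_neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
  bool has_pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
  return !(has_neg && has_pos);
}

static bool coplanar_tri_tri(const Vec3 &n, const Vec3 &v0, const Vec3 &v1,
                             const Vec3 &v2, const Vec3 &u0, const Vec3 &u1,
                             const Vec3 &u2) {
  // project onto the dominant axis plane
  double a[3] = {std::fabs(n.x), std::fabs(n.y), std::fabs(n.z)};
  int i0 = 0, i1 = 1;
  if (a[0] > a[1] && a[0] > a[2]) { i0 = 1; i1 = 2; }
  else if (a[1] > a[2]) { i0 = 0; i1 = 2; }
  auto proj = [&](const Vec3 &v, double *out) {
    double c[3] = {v.x, v.y, v.z};
    out[0] = c[i0]; out[1] = c[i1];
  };
  double V0[2], V1[2], V2[2], U0[2], U1[2], U2[2];
  proj(v0, V0); proj(v1, V1); proj(v2, V2);
  proj(u0, U0); proj(u1, U1); proj(u2, U2);
  if (edge_against_tri(V0, V1, U0, U1, U2)) return true;
  if (edge_against_tri(V1, V2, U0, U1, U2)) return true;
  if (edge_against_tri(V2, V0, U0, U1, U2)) return true;
  if (point_in_tri_2d(V0, U0, U1, U2)) return true;
  if (point_in_tri_2d(U0, V0, V1, V2)) return true;
  return false;
}

// Interval computation (unscaled): returns the two parameters along the
// intersection line where the triangle crosses the other triangle's plane.
static bool compute_interval(double vv0, double vv1, double vv2, double d0,
                             double d1, double d2, double &t0, double &t1) {
  // pick the vertex that lies alone on one side of the plane
  if (d0 * d1 > 0.0) {        // v2 alone
    t0 = vv2 + (vv0 - vv2) * d2 / (d2 - d0);
    t1 = vv2 + (vv1 - vv2) * d2 / (d2 - d1);
  } else if (d0 * d2 > 0.0) { // v1 alone
    t0 = vv1 + (vv0 - vv1) * d1 / (d1 - d0);
    t1 = vv1 + (vv2 - vv1) * d1 / (d1 - d2);
  } else if (d1 * d2 > 0.0 || d0 != 0.0) { // v0 alone
    t0 = vv0 + (vv1 - vv0) * d0 / (d0 - d1);
    t1 = vv0 + (vv2 - vv0) * d0 / (d0 - d2);
  } else if (d1 != 0.0) {
    t0 = vv1 + (vv0 - vv1) * d1 / (d1 - d0);
    t1 = vv1 + (vv2 - vv1) * d1 / (d1 - d2);
  } else if (d2 != 0.0) {
    t0 = vv2 + (vv0 - vv2) * d2 / (d2 - d0);
    t1 = vv2 + (vv1 - vv2) * d2 / (d2 - d1);
  } else {
    return true; // coplanar
  }
  return false;
}

static bool tri_tri_intersect(const Vec3 &v0, const Vec3 &v1, const Vec3 &v2,
                              const Vec3 &u0, const Vec3 &u1, const Vec3 &u2) {
  const double EPS = 1e-12;
  Vec3 n1 = (v1 - v0).cross(v2 - v0);
  double d1 = -n1.dot(v0);
  double du0 = n1.dot(u0) + d1, du1 = n1.dot(u1) + d1, du2 = n1.dot(u2) + d1;
  if (std::fabs(du0) < EPS) du0 = 0.0;
  if (std::fabs(du1) < EPS) du1 = 0.0;
  if (std::fabs(du2) < EPS) du2 = 0.0;
  double du0du1 = du0 * du1, du0du2 = du0 * du2;
  if (du0du1 > 0.0 && du0du2 > 0.0) return false;

  Vec3 n2 = (u1 - u0).cross(u2 - u0);
  double d2 = -n2.dot(u0);
  double dv0 = n2.dot(v0) + d2, dv1 = n2.dot(v1) + d2, dv2 = n2.dot(v2) + d2;
  if (std::fabs(dv0) < EPS) dv0 = 0.0;
  if (std::fabs(dv1) < EPS) dv1 = 0.0;
  if (std::fabs(dv2) < EPS) dv2 = 0.0;
  double dv0dv1 = dv0 * dv1, dv0dv2 = dv0 * dv2;
  if (dv0dv1 > 0.0 && dv0dv2 > 0.0) return false;

  Vec3 dir = n1.cross(n2);
  double a[3] = {std::fabs(dir.x), std::fabs(dir.y), std::fabs(dir.z)};
  int idx = 0;
  if (a[1] > a[0]) idx = 1;
  if (a[2] > a[idx]) idx = 2;
  auto comp = [&](const Vec3 &v) {
    return idx == 0 ? v.x : (idx == 1 ? v.y : v.z);
  };
  double vp0 = comp(v0), vp1 = comp(v1), vp2 = comp(v2);
  double up0 = comp(u0), up1 = comp(u1), up2 = comp(u2);

  double isect1[2], isect2[2];
  bool cop1 = compute_interval(vp0, vp1, vp2, dv0, dv1, dv2, isect1[0], isect1[1]);
  bool cop2 = compute_interval(up0, up1, up2, du0, du1, du2, isect2[0], isect2[1]);
  if (cop1 || cop2)
    return coplanar_tri_tri(n1, v0, v1, v2, u0, u1, u2);
  if (isect1[0] > isect1[1]) std::swap(isect1[0], isect1[1]);
  if (isect2[0] > isect2[1]) std::swap(isect2[0], isect2[1]);
  // strict overlap: touching at a single point is not a proper intersection
  return isect1[1] > isect2[0] + EPS && isect2[1] > isect1[0] + EPS;
}

// [[Rcpp::export]]
LogicalVector cpp_self_intersections(NumericMatrix vertices, IntegerMatrix faces0) {
  int nf = faces0.nrow();
  LogicalVector hit(nf, false);
  // AABBs
  std::vector<double> bmin(3 * nf), bmax(3 * nf);
  for (int t = 0; t < nf; ++t)
    for (int k = 0; k < 3; ++k) {
      double a = vertices(faces0(t, 0), k), b = vertices(faces0(t, 1), k),
             c = vertices(faces0(t, 2), k);
      bmin[3 * t + k] = std::min(a, std::min(b, c));
      bmax[3 * t + k] = std::max(a, std::max(b, c));
    }
  // sort by x-min for a sweep to prune pairs
  std::vector<int> idx(nf);
  for (int i = 0; i < nf; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return bmin[3 * a] < bmin[3 * b]; });
  for (int ii = 0; ii < nf; ++ii) {
    int t = idx[ii];
    for (int jj = ii + 1; jj < nf; ++jj) {
      int s = idx[jj];
      if (bmin[3 * s] > bmax[3 * t]) break;  // sweep cut on x
      bool overlap = true;
      for (int k = 1; k < 3; ++k)
        if (bmin[3 * s + k] > bmax[3 * t + k] || bmin[3 * t + k] > bmax[3 * s + k]) {
          overlap = false;
          break;
        }
      if (!overlap) continue;
      // skip adjacent faces (sharing >= 1 vertex)
      bool shared = false;
      for (int a = 0; a < 3 && !shared; ++a)
        for (int b = 0; b < 3; ++b)
          if (faces0(t, a) == faces0(s, b)) { shared = true; break; }
      if (shared) continue;
      Vec3 v0(vertices(faces0(t, 0), 0), vertices(faces0(t, 0), 1), vertices(faces0(t, 0), 2));
      Vec3 v1(vertices(faces0(t, 1), 0), vertices(faces0(t, 1), 1), vertices(faces0(t, 1), 2));
      Vec3 v2(vertices(faces0(t, 2), 0), vertices(faces0(t, 2), 1), vertices(faces0(t, 2), 2));
      Vec3 u0(vertices(faces0(s, 0), 0), vertices(faces0(s, 0), 1), vertices(faces0(s, 0), 2));
      Vec3 u1(vertices(faces0(s, 1), 0), vertices(faces0(s, 1), 1), vertices(faces0(s, 1), 2));
      Vec3 u2(vertices(faces0(s, 2), 0), vertices(faces0(s, 2), 1), vertices(faces0(s, 2), 2));
      if (tri_tri_intersect(v0, v1, v2, u0, u1, u2)) {
        hit[t] = true;
        hit[s] = true;
      }
    }
  }
  return hit;
}

// ---- kd-tree nearest neighbour between point sets ----

struct KDNode {
  int axis;
  double split;
  int left, right;
  int start, count;
};

struct KDTree {
  std::vector<KDNode> nodes;
  std::vector<int> order;
  const NumericMatrix *P;

  int build(int start, int count) {
    KDNode node;
    if (count <= 8) {
      node.axis = -1;
      node.left = node.right = -1;
      node.start = start;
      node.count = count;
      nodes.push_back(node);
      return (int)nodes.size() - 1;
    }
    const NumericMatrix &p = *P;
    double mn[3] = {1e300, 1e300, 1e300}, mx[3] = {-1e300, -1e300, -1e300};
    for (int i = start; i < start + count; ++i)
      for (int k = 0; k < 3; ++k) {
        mn[k] = std::min(mn[k], p(order[i], k));
        mx[k] = std::max(mx[k], p(order[i], k));
      }
    int axis = 0;
    for (int k = 1; k < 3; ++k)
      if (mx[k] - mn[k] > mx[axis] - mn[axis]) axis = k;
    std::nth_element(order.begin() + start, order.begin() + start + count / 2,
                     order.begin() + start + count,
                     [&](int a, int b) { return p(a, axis) < p(b, axis); });
    int mid = count / 2;
    node.axis = axis;
    node.split = p(order[start + mid], axis);
    node.start = -1;
    node.count = 0;
    int self = (int)nodes.size();
    nodes.push_back(node);
    int l = build(start, mid);
    int r = build(start + mid, count - mid);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }

  void query(const double *q, double &best2, int &best, int ni) const {
    const KDNode &n = nodes[ni];
    const NumericMatrix &p = *P;
    if (n.axis < 0) {
      for (int i = n.start; i < n.start + n.count; ++i) {
        int j = order[i];
        double dx = q[0] - p(j, 0), dy = q[1] - p(j, 1), dz = q[2] - p(j, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best2) { best2 = d2; best = j; }
      }
      return;
    }
    double diff = q[n.axis] - n.split;
    int near = diff < 0 ? n.left : n.right;
    int far = diff < 0 ? n.right : n.left;
    query(q, best2, best, near);
    if (diff * diff < best2) query(q, best2, best, far);
  }
};

// [[Rcpp::export]]
List cpp_nn(NumericMatrix query, NumericMatrix ref) {
  int n = query.nrow(), m = ref.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  KDTree kd;
  kd.P = &ref;
  kd.order.resize(m);
  for (int i = 0; i < m; ++i) kd.order[i] = i;
  kd.build(0, m);
  for (int i = 0; i < n; ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    double best2 = std::numeric_limits<double>::infinity();
    int best = -1;
    kd.query(q, best2, best, 0);
    idx[i] = best + 1;  // 1-based for R
    dist[i] = std::sqrt(best2);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
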