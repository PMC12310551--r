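// Ray-casting core: watertight ray-triangle intersection, a median-split BVH,
// and the five-face sensor-rig tracer. The BVH traversal uses the identical
// per-triangle test as the brute-force path, so both return equal nearest-hit
// distances (a contract the test suite asserts exactly).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double T_MIN = 1e-12;  // reject hits at (numerically) zero distance

// ---------------------------------------------------------------------------
// Watertight ray-triangle intersection (shear/scale formulation).
// Edge-on and vertex-grazing rays resolve deterministically: any hit with
// consistently signed barycentrics (zeros allowed) counts as a hit.
// ---------------------------------------------------------------------------
struct RayCtx {
  double org[3];
  int kx, ky, kz;
  double Sx, Sy, Sz;
};

static inline RayCtx make_ray(const double* o, const double* d) {
  RayCtx r;
  r.org[0] = o[0]; r.org[1] = o[1]; r.org[2] = o[2];
  int kz = 0;
  double m = std::fabs(d[0]);
  if (std::fabs(d[1]) > m) { m = std::fabs(d[1]); kz = 1; }
  if (std::fabs(d[2]) > m) { kz = 2; }
  int kx = kz + 1; if (kx == 3) kx = 0;
  int ky = kx + 1; if (ky == 3) ky = 0;
  if (d[kz] < 0.0) std::swap(kx, ky);
  r.kx = kx; r.ky = ky; r.kz = kz;
  r.Sx = d[kx] / d[kz];
  r.Sy = d[ky] / d[kz];
  r.Sz = 1.0 / d[kz];
  return r;
}

static inline double tri_hit(const RayCtx& r, const double* A, const double* B,
                             const double* C) {
  const double Akz = A[r.kz] - r.org[r.kz];
  const double Bkz = B[r.kz] - r.org[r.kz];
  const double Ckz = C[r.kz] - r.org[r.kz];
  const double Ax = (A[r.kx] - r.org[r.kx]) - r.Sx * Akz;
  const double Ay = (A[r.ky] - r.org[r.ky]) - r.Sy * Akz;
  const double Bx = (B[r.kx] - r.org[r.kx]) - r.Sx * Bkz;
  const double By = (B[r.ky] - r.org[r.ky]) - r.Sy * Bkz;
  const double Cx = (C[r.kx] - r.org[r.kx]) - r.Sx * Ckz;
  const double Cy = (C[r.ky] - r.org[r.ky]) - r.Sy * Ckz;

  const double U = Cx * By - Cy * Bx;
  const double V = Ax * Cy - Ay * Cx;
  const double W = Bx * Ay - By * Ax;
  if ((U < 0.0 || V < 0.0 || W < 0.0) && (U > 0.0 || V > 0.0 || W > 0.0))
    return INF;
  const double det = U + V + W;
  if (det == 0.0) return INF;

  const double Az = r.Sz * Akz;
  const double Bz = r.Sz * Bkz;
  const double Cz = r.Sz * Ckz;
  const double t = (U * Az + V * Bz + W * Cz) / det;
  return (t > T_MIN) ? t : INF;
}

// ---------------------------------------------------------------------------
// Mesh container + brute-force nearest hit
// ---------------------------------------------------------------------------
struct Mesh {
  const double* V;  // n x 3, column-major from R
  int nv;
  std::vector<int> f0, f1, f2;  // 0-based
  void vertex(int i, double* out) const {
    out[0] = V[i]; out[1] = V[i + nv]; out[2] = V[i + 2 * nv];
  }
};

static Mesh make_mesh(const NumericMatrix& V, const IntegerMatrix& F) {
  Mesh m;
  m.V = V.begin();
  m.nv = V.nrow();
  const int nf = F.nrow();
  m.f0.resize(nf); m.f1.resize(nf); m.f2.resize(nf);
  for (int k = 0; k < nf; ++k) {
    m.f0[k] = F(k, 0) - 1;
    m.f1[k] = F(k, 1) - 1;
    m.f2[k] = F(k, 2) - 1;
    if (m.f0[k] < 0 || m.f0[k] >= m.nv || m.f1[k] < 0 || m.f1[k] >= m.nv ||
        m.f2[k] < 0 || m.f2[k] >= m.nv)
      stop("face index out of range in row %d", k + 1);
  }
  return m;
}

static double brute_nearest(const Mesh& m, const RayCtx& r) {
  double best = INF;
  double A[3], B[3], C[3];
  const int nf = (int)m.f0.size();
  for (int k = 0; k < nf; ++k) {
    m.vertex(m.f0[k], A); m.vertex(m.f1[k], B); m.vertex(m.f2[k], C);
    const double t = tri_hit(r, A, B, C);
    if (t < best) best = t;
  }
  return best;
}

// ---------------------------------------------------------------------------
// BVH: median split on the widest centroid axis, leaf size <= 4
// ---------------------------------------------------------------------------
struct BVHNode {
  double bmin[3], bmax[3];
  int left = -1, right = -1;  // internal children
  int start = 0, count = 0;   // leaf triangle range (count > 0 => leaf)
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> prim;            // triangle ids, reordered during build
  std::vector<double> cent;         // 3 * ntri centroids (build scratch)
  std::vector<double> tmin, tmax;   // per-tri bounds (build scratch)
};

static void node_bounds(BVH& b, const int lo, const int hi, BVHNode& nd) {
  for (int a = 0; a < 3; ++a) { nd.bmin[a] = INF; nd.bmax[a] = -INF; }
  for (int i = lo; i < hi; ++i) {
    const int k = b.prim[i];
    for (int a = 0; a < 3; ++a) {
      nd.bmin[a] = std::min(nd.bmin[a], b.tmin[3 * k + a]);
      nd.bmax[a] = std::max(nd.bmax[a], b.tmax[3 * k + a]);
    }
  }
}

static int bvh_split(BVH& b, int lo, int hi) {
  const int id = (int)b.nodes.size();
  b.nodes.push_back(BVHNode());
  node_bounds(b, lo, hi, b.nodes[id]);
  if (hi - lo <= 4) {
    b.nodes[id].start = lo;
    b.nodes[id].count = hi - lo;
    return id;
  }
  // widest axis of centroid extent
  double cmin[3] = {INF, INF, INF}, cmax[3] = {-INF, -INF, -INF};
  for (int i = lo; i < hi; ++i) {
    const int k = b.prim[i];
    for (int a = 0; a < 3; ++a) {
      cmin[a] = std::min(cmin[a], b.cent[3 * k + a]);
      cmax[a] = std::max(cmax[a], b.cent[3 * k + a]);
    }
  }
  int axis = 0;
  double w = cmax[0] - cmin[0];
  if (cmax[1] - cmin[1] > w) { w = cmax[1] - cmin[1]; axis = 1; }
  if (cmax[2] - cmin[2] > w) { w = cmax[2] - cmin[2]; axis = 2; }
  const int mid = (lo + hi) / 2;
  if (w <= 0.0) {
    // degenerate spread: split by index order
  } else {
    std::nth_element(b.prim.begin() + lo, b.prim.begin() + mid,
                     b.prim.begin() + hi, [&](int p, int q) {
                       return b.cent[3 * p + axis] < b.cent[3 * q + axis];
                     });
  }
  const int l = bvh_split(b, lo, mid);
  const int r = bvh_split(b, mid, hi);
  b.nodes[id].left = l;
  b.nodes[id].right = r;
  return id;
}

static BVH bvh_build(const Mesh& m) {
  BVH b;
  const int nf = (int)m.f0.size();
  b.prim.resize(nf);
  b.cent.resize(3 * nf);
  b.tmin.resize(3 * nf);
  b.tmax.resize(3 * nf);
  double P[3][3];
  for (int k = 0; k < nf; ++k) {
    b.prim[k] = k;
    m.vertex(m.f0[k], P[0]); m.vertex(m.f1[k], P[1]); m.vertex(m.f2[k], P[2]);
    for (int a = 0; a < 3; ++a) {
      b.tmin[3 * k + a] = std::min({P[0][a], P[1][a], P[2][a]});
      b.tmax[3 * k + a] = std::max({P[0][a], P[1][a], P[2][a]});
      b.cent[3 * k + a] = (P[0][a] + P[1][a] + P[2][a]) / 3.0;
    }
  }
  if (nf > 0) bvh_split(b, 0, nf);
  return b;
}

// slab test: does the box intersect the ray within [0, tbest]?
static inline bool box_hit(const BVHNode& nd, const double* o, const double* d,
                           double tbest) {
  double t0 = 0.0, t1 = tbest;
  for (int a = 0; a < 3; ++a) {
    if (d[a] == 0.0) {
      if (o[a] < nd.bmin[a] || o[a] > nd.bmax[a]) return false;
    } else {
      const double inv = 1.0 / d[a];
      double ta = (nd.bmin[a] - o[a]) * inv;
      double tb = (nd.bmax[a] - o[a]) * inv;
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 > t1) return false;
    }
  }
  return true;
}

static double bvh_nearest(const Mesh& m, const BVH& b, const double* o,
                          const double* d, const RayCtx& r) {
  if (b.nodes.empty()) return INF;
  double best = INF;
  double A[3], B[3], C[3];
  int stack[128];
  int sp = 0;
  stack[sp++] = 0;
  while (sp > 0) {
    const BVHNode& nd = b.nodes[stack[--sp]];
    if (!box_hit(nd, o, d, best)) continue;
    if (nd.count > 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        const int k = b.prim[i];
        m.vertex(m.f0[k], A); m.vertex(m.f1[k], B); m.vertex(m.f2[k], C);
        const double t = tri_hit(r, A, B, C);
        if (t < best) best = t;
      }
    } else {
      stack[sp++] = nd.left;
      stack[sp++] = nd.right;
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// Nearest-hit distances for a batch of rays; Inf encodes a miss.
// [[Rcpp::export]]
NumericVector cpp_ray_trace(NumericMatrix V, IntegerMatrix F,
                            NumericMatrix origins, NumericMatrix dirs,
                            bool brute = false) {
  const Mesh m = make_mesh(V, F);
  const int n = origins.nrow();
  if (dirs.nrow() != n) stop("origins and dirs must have equal row counts");
  NumericVector out(n);
  BVH b;
  if (!brute) b = bvh_build(m);
  double o[3], d[3];
  for (int i = 0; i < n; ++i) {
    o[0] = origins(i, 0); o[1] = origins(i, 1); o[2] = origins(i, 2);
    d[0] = dirs(i, 0); d[1] = dirs(i, 1); d[2] = dirs(i, 2);
    if (d[0] == 0.0 && d[1] == 0.0 && d[2] == 0.0)
      stop("degenerate (zero) ray direction in row %d", i + 1);
    const RayCtx r = make_ray(o, d);
    out[i] = brute ? brute_nearest(m, r) : bvh_nearest(m, b, o, d, r);
  }
  return out;
}

// Trace one primary ray per pixel center for the five-face rig.
// `bases` is 5 x 9: per face the camera right, up and view vectors
// (rx ry rz ux uy uz wx wy wz). Pixel centers follow the tangent-plane grid
// x_j = (2j-1)/res - 1 (columns, left to right), y_i = 1 - (2i-1)/res (rows,
// top to bottom); tan(fov/2) = 1 for the 90-degree faces. Returns a logical
// vector of length 5*res*res, face-major then column-major (i fastest),
// TRUE = occluded.
// [[Rcpp::export]]
LogicalVector cpp_trace_rig(NumericMatrix V, IntegerMatrix F,
                            NumericVector origin, NumericMatrix bases,
                            int res) {
  if (bases.nrow() != 5 || bases.ncol() != 9) stop("bases must be 5 x 9");
  if (res < 2) stop("res must be >= 2");
  const Mesh m = make_mesh(V, F);
  const BVH b = bvh_build(m);
  const double o[3] = {origin[0], origin[1], origin[2]};
  LogicalVector out((R_xlen_t)5 * res * res);
  R_xlen_t pos = 0;
  for (int f = 0; f < 5; ++f) {
    const double rx = bases(f, 0), ry = bases(f, 1), rz = bases(f, 2);
    const double ux = bases(f, 3), uy = bases(f, 4), uz = bases(f, 5);
    const double wx = bases(f, 6), wy = bases(f, 7), wz = bases(f, 8);
    for (int j = 1; j <= res; ++j) {
      const double x = (2.0 * j - 1.0) / res - 1.0;
      for (int i = 1; i <= res; ++i) {
        const double y = 1.0 - (2.0 * i - 1.0) / res;
        double d[3] = {wx + x * rx + y * ux, wy + x * ry + y * uy,
                       wz + x * rz + y * uz};
        const double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
        d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
        const RayCtx r = make_ray(o, d);
        out[pos++] = (bvh_nearest(m, b, o, d, r) < INF);
      }
    }
  }
  return out;
}
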