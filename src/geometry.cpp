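#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Low-level mesh predicates. Meshes arrive as an n x 3 vertex matrix and an
// m x 3 one-based face index matrix; closedness is validated on the R side.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

inline Vec3 row3(const NumericMatrix &m, int i) {
  return {m(i, 0), m(i, 1), m(i, 2)};
}

// Moeller-Trumbore ray/triangle intersection restricted to t in
// [tmin, tmax]. Returns 0 = miss, 1 = clean hit, 2 = grazing hit (the
// barycentric coordinates or t sit within `graze` of a boundary, so the
// parity count cannot be trusted and the caller should retry with another
// ray direction).
int ray_tri(const Vec3 &orig, const Vec3 &dir, const Vec3 &v0, const Vec3 &v1,
            const Vec3 &v2, double tmin, double tmax, double graze,
            double &t_out) {
  const Vec3 e1 = vsub(v1, v0);
  const Vec3 e2 = vsub(v2, v0);
  const Vec3 p = vcross(dir, e2);
  const double det = vdot(e1, p);
  if (std::fabs(det) < 1e-14) return 0; // parallel (or degenerate triangle)
  const double inv = 1.0 / det;
  const Vec3 s = vsub(orig, v0);
  const double u = vdot(s, p) * inv;
  if (u < -graze || u > 1.0 + graze) return 0;
  const Vec3 q = vcross(s, e1);
  const double v = vdot(dir, q) * inv;
  if (v < -graze || u + v > 1.0 + graze) return 0;
  const double t = vdot(e2, q) * inv;
  if (t < tmin - graze || t > tmax + graze) return 0;
  t_out = t;
  if (u < graze || v < graze || u + v > 1.0 - graze || t < tmin + graze ||
      t > tmax - graze)
    return 2;
  return 1;
}

// Parity of ray crossings from `p` in direction `dir` over the whole mesh.
// Returns -1 when any grazing hit makes the parity unreliable.
int parity_along(const NumericMatrix &V, const IntegerMatrix &F, const Vec3 &p,
                 const Vec3 &dir, double graze) {
  int crossings = 0;
  double t;
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const Vec3 v0 = row3(V, F(f, 0) - 1);
    const Vec3 v1 = row3(V, F(f, 1) - 1);
    const Vec3 v2 = row3(V, F(f, 2) - 1);
    const int h =
        ray_tri(p, dir, v0, v1, v2, 0.0, R_PosInf, graze, t);
    if (h == 2) return -1;
    if (h == 1) ++crossings;
  }
  return crossings % 2;
}

const double DIRS[5][3] = {
    {0.5380236517, 0.6710436067, 0.5103362041},
    {-0.2603550728, 0.8237741372, 0.5036937323},
    {0.7931405317, -0.1193279380, 0.5972309699},
    {0.1136089178, -0.4392736084, -0.8911364486},
    {-0.6712095767, -0.5402357374, 0.5075823290}};

bool point_inside(const NumericMatrix &V, const IntegerMatrix &F,
                  const Vec3 &p, double graze) {
  for (int k = 0; k < 5; ++k) {
    Vec3 d = {DIRS[k][0], DIRS[k][1], DIRS[k][2]};
    const int par = parity_along(V, F, p, d, graze);
    if (par >= 0) return par == 1;
  }
  // All candidate directions grazed: the point is (numerically) on the
  // surface; membership is undefined within tolerance, report "outside".
  return false;
}

// Segment/triangle intersection used by the collision test.
bool seg_tri(const Vec3 &a, const Vec3 &b, const Vec3 &v0, const Vec3 &v1,
             const Vec3 &v2) {
  const Vec3 d = vsub(b, a);
  double t;
  return ray_tri(a, d, v0, v1, v2, 0.0, 1.0, 0.0, t) != 0;
}

struct BBox {
  double lo[3], hi[3];
};

BBox face_bbox(const NumericMatrix &V, const IntegerMatrix &F, int f) {
  BBox b;
  for (int c = 0; c < 3; ++c) {
    double a0 = V(F(f, 0) - 1, c), a1 = V(F(f, 1) - 1, c),
           a2 = V(F(f, 2) - 1, c);
    b.lo[c] = std::min(a0, std::min(a1, a2));
    b.hi[c] = std::max(a0, std::max(a1, a2));
  }
  return b;
}

inline bool bbox_overlap(const BBox &a, const BBox &b, double pad) {
  for (int c = 0; c < 3; ++c)
    if (a.hi[c] + pad < b.lo[c] || b.hi[c] + pad < a.lo[c]) return false;
  return true;
}

} // namespace

// [[Rcpp::export(name = ".cpp_points_in_mesh")]]
LogicalVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix P, double graze = 1e-9) {
  const int n = P.nrow();
  LogicalVector out(n);
  // Mesh bounding box rejects most far-field queries cheaply.
  BBox mb;
  for (int c = 0; c < 3; ++c) {
    mb.lo[c] = R_PosInf;
    mb.hi[c] = R_NegInf;
  }
  for (int i = 0; i < V.nrow(); ++i)
    for (int c = 0; c < 3; ++c) {
      mb.lo[c] = std::min(mb.lo[c], V(i, c));
      mb.hi[c] = std::max(mb.hi[c], V(i, c));
    }
  for (int i = 0; i < n; ++i) {
    const Vec3 p = row3(P, i);
    bool inside_box = p.x >= mb.lo[0] && p.x <= mb.hi[0] && p.y >= mb.lo[1] &&
                      p.y <= mb.hi[1] && p.z >= mb.lo[2] && p.z <= mb.hi[2];
    out[i] = inside_box ? point_inside(V, F, p, graze) : false;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_mesh_collision")]]
bool cpp_mesh_collision(NumericMatrix V1, IntegerMatrix F1, NumericMatrix V2,
                        IntegerMatrix F2) {
  const int n1 = F1.nrow(), n2 = F2.nrow();
  std::vector<BBox> b1(n1), b2(n2);
  BBox g1, g2;
  for (int c = 0; c < 3; ++c) {
    g1.lo[c] = g2.lo[c] = R_PosInf;
    g1.hi[c] = g2.hi[c] = R_NegInf;
  }
  for (int f = 0; f < n1; ++f) {
    b1[f] = face_bbox(V1, F1, f);
    for (int c = 0; c < 3; ++c) {
      g1.lo[c] = std::min(g1.lo[c], b1[f].lo[c]);
      g1.hi[c] = std::max(g1.hi[c], b1[f].hi[c]);
    }
  }
  for (int f = 0; f < n2; ++f) {
    b2[f] = face_bbox(V2, F2, f);
    for (int c = 0; c < 3; ++c) {
      g2.lo[c] = std::min(g2.lo[c], b2[f].lo[c]);
      g2.hi[c] = std::max(g2.hi[c], b2[f].hi[c]);
    }
  }
  if (!bbox_overlap(g1, g2, 0.0)) return false;

  // Surface crossing: any edge of one mesh piercing a face of the other.
  for (int f1 = 0; f1 < n1; ++f1) {
    if (!bbox_overlap(b1[f1], g2, 0.0)) continue;
    const Vec3 a0 = row3(V1, F1(f1, 0) - 1);
    const Vec3 a1 = row3(V1, F1(f1, 1) - 1);
    const Vec3 a2 = row3(V1, F1(f1, 2) - 1);
    for (int f2 = 0; f2 < n2; ++f2) {
      if (!bbox_overlap(b1[f1], b2[f2], 0.0)) continue;
      const Vec3 c0 = row3(V2, F2(f2, 0) - 1);
      const Vec3 c1 = row3(V2, F2(f2, 1) - 1);
      const Vec3 c2 = row3(V2, F2(f2, 2) - 1);
      if (seg_tri(a0, a1, c0, c1, c2) || seg_tri(a1, a2, c0, c1, c2) ||
          seg_tri(a2, a0, c0, c1, c2) || seg_tri(c0, c1, a0, a1, a2) ||
          seg_tri(c1, c2, a0, a1, a2) || seg_tri(c2, c0, a0, a1, a2))
        return true;
    }
  }

  // No crossing: either disjoint or one mesh entirely inside the other.
  if (point_inside(V2, F2, row3(V1, 0), 1e-9)) return true;
  if (point_inside(V1, F1, row3(V2, 0), 1e-9)) return true;
  return false;
}
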