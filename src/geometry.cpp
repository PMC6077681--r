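#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Isosurface extraction: marching tetrahedra on a regular grid.
//
// Each grid cube is split into 6 tetrahedra sharing the main diagonal
// (corner 0 -> corner 7).  Face diagonals of the decomposition agree between
// neighbouring cubes, and each tetrahedron case is unambiguous, so the
// extracted surface is watertight whenever the negative (interior) region
// stays strictly inside the grid.  Vertices are welded through an edge->index
// map keyed on the global ids of the two grid nodes an edge connects.
// ---------------------------------------------------------------------------

static const int TET[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

// corner bit layout: bit0 = +x, bit1 = +y, bit2 = +z
static const int CX[8] = {0, 1, 0, 1, 0, 1, 0, 1};
static const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
static const int CZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};

struct MTState {
  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  const double *field;
  const double *xs, *ys, *zs;
  int nx, ny, nz;

  inline uint64_t nid(int ix, int iy, int iz) const {
    return (uint64_t)ix + (uint64_t)nx * ((uint64_t)iy + (uint64_t)ny * (uint64_t)iz);
  }
  inline double fval(uint64_t id) const { return field[id]; }

  // interpolated zero-crossing vertex on the edge between grid nodes a and b
  int edge_vertex(uint64_t a, uint64_t b) {
    if (a > b) std::swap(a, b);
    uint64_t key = a * (uint64_t)(nx) * (uint64_t)(ny) * (uint64_t)(nz) + b;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double fa = field[a], fb = field[b];
    double t = fa / (fa - fb);
    // keep vertices clear of grid nodes: crossings from different edges
    // meeting at a node must stay farther apart than the duplicate-vertex
    // merge tolerance or welding would open the surface
    if (t < 2e-4) t = 2e-4;
    if (t > 1.0 - 2e-4) t = 1.0 - 2e-4;
    int axi = (int)(a % nx), ayi = (int)((a / nx) % ny), azi = (int)(a / ((uint64_t)nx * ny));
    int bxi = (int)(b % nx), byi = (int)((b / nx) % ny), bzi = (int)(b / ((uint64_t)nx * ny));
    double px = xs[axi] + t * (xs[bxi] - xs[axi]);
    double py = ys[ayi] + t * (ys[byi] - ys[ayi]);
    double pz = zs[azi] + t * (zs[bzi] - zs[azi]);
    int idx = (int)vx.size();
    vx.push_back(px); vy.push_back(py); vz.push_back(pz);
    edge_vert[key] = idx;
    return idx;
  }

  void tri(int a, int b, int c) { f0.push_back(a); f1.push_back(b); f2.push_back(c); }

  // (i,j,k,l) must be an even permutation of the positively oriented tet
  void lone_inside(uint64_t vi, uint64_t vj, uint64_t vk, uint64_t vl, bool rev) {
    int a = edge_vertex(vi, vj), b = edge_vertex(vi, vk), c = edge_vertex(vi, vl);
    if (rev) tri(a, c, b); else tri(a, b, c);
  }
  void pair_inside(uint64_t va, uint64_t vb, uint64_t vc, uint64_t vd) {
    int pac = edge_vertex(va, vc), pad = edge_vertex(va, vd);
    int pbd = edge_vertex(vb, vd), pbc = edge_vertex(vb, vc);
    tri(pac, pad, pbd); tri(pac, pbd, pbc);
  }

  void do_tet(const uint64_t g[4]) {
    int mask = 0;
    for (int i = 0; i < 4; ++i) if (field[g[i]] < 0.0) mask |= (1 << i);
    switch (mask) {
    case 0: case 15: return;
    case 1:  lone_inside(g[0], g[1], g[2], g[3], false); return;
    case 2:  lone_inside(g[1], g[0], g[3], g[2], false); return;
    case 4:  lone_inside(g[2], g[0], g[1], g[3], false); return;
    case 8:  lone_inside(g[3], g[1], g[0], g[2], false); return;
    case 14: lone_inside(g[0], g[1], g[2], g[3], true);  return;
    case 13: lone_inside(g[1], g[0], g[3], g[2], true);  return;
    case 11: lone_inside(g[2], g[0], g[1], g[3], true);  return;
    case 7:  lone_inside(g[3], g[1], g[0], g[2], true);  return;
    case 3:  pair_inside(g[0], g[1], g[2], g[3]); return;
    case 5:  pair_inside(g[0], g[2], g[3], g[1]); return;
    case 9:  pair_inside(g[0], g[3], g[1], g[2]); return;
    case 6:  pair_inside(g[1], g[2], g[0], g[3]); return;
    case 10: pair_inside(g[1], g[3], g[2], g[0]); return;
    case 12: pair_inside(g[2], g[3], g[0], g[1]); return;
    }
  }
};

// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector field, NumericVector xs,
                             NumericVector ys, NumericVector zs) {
  MTState st;
  st.nx = xs.size(); st.ny = ys.size(); st.nz = zs.size();
  if ((R_xlen_t)st.nx * st.ny * st.nz != field.size())
    stop("field length does not match grid dimensions");
  st.field = field.begin();
  st.xs = xs.begin(); st.ys = ys.begin(); st.zs = zs.begin();

  for (int iz = 0; iz + 1 < st.nz; ++iz)
    for (int iy = 0; iy + 1 < st.ny; ++iy)
      for (int ix = 0; ix + 1 < st.nx; ++ix) {
        uint64_t corner[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          corner[c] = st.nid(ix + CX[c], iy + CY[c], iz + CZ[c]);
          if (st.field[corner[c]] < 0.0) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          uint64_t g[4] = {corner[TET[t][0]], corner[TET[t][1]],
                           corner[TET[t][2]], corner[TET[t][3]]};
          st.do_tet(g);
        }
      }

  int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i]; }
  for (int i = 0; i < nf; ++i) { F(i, 0) = st.f0[i] + 1; F(i, 1) = st.f1[i] + 1; F(i, 2) = st.f2[i] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Ray casting (Moller-Trumbore) over all faces: returns every crossing's
// signed distance t >= 0 along the ray plus whether the ray enters
// (dir . outward-normal < 0) at that crossing.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List raycast_cpp(NumericMatrix V, IntegerMatrix F,
                 NumericVector origin, NumericVector dir, double tmin) {
  const double EPS = 1e-12;
  int nf = F.nrow();
  std::vector<double> ts; std::vector<int> ent; std::vector<int> face;
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double dx = dir[0], dy = dir[1], dz = dir[2];
  for (int i = 0; i < nf; ++i) {
    int a = F(i, 0) - 1, b = F(i, 1) - 1, c = F(i, 2) - 1;
    double e1x = V(b,0)-V(a,0), e1y = V(b,1)-V(a,1), e1z = V(b,2)-V(a,2);
    double e2x = V(c,0)-V(a,0), e2y = V(c,1)-V(a,1), e2z = V(c,2)-V(a,2);
    double px = dy*e2z - dz*e2y, py = dz*e2x - dx*e2z, pz = dx*e2y - dy*e2x;
    double det = e1x*px + e1y*py + e1z*pz;
    if (std::fabs(det) < EPS) continue;
    double inv = 1.0 / det;
    double tx = ox - V(a,0), ty = oy - V(a,1), tz = oz - V(a,2);
    double u = (tx*px + ty*py + tz*pz) * inv;
    if (u < -1e-10 || u > 1.0 + 1e-10) continue;
    double qx = ty*e1z - tz*e1y, qy = tz*e1x - tx*e1z, qz = tx*e1y - ty*e1x;
    double v = (dx*qx + dy*qy + dz*qz) * inv;
    if (v < -1e-10 || u + v > 1.0 + 1e-10) continue;
    double t = (e2x*qx + e2y*qy + e2z*qz) * inv;
    if (t < tmin) continue;
    ts.push_back(t);
    // det = e1 . (dir x e2) = -dir . (e1 x e2): entering when det > 0
    ent.push_back(det > 0 ? 1 : 0);
    face.push_back(i + 1);
  }
  return List::create(_["t"] = wrap(ts), _["entering"] = wrap(ent),
                      _["face"] = wrap(face));
}

// ---------------------------------------------------------------------------
// Batch point containment: +Z ray parity with a uniform 2D (x,y) grid over
// face bounding boxes as the acceleration structure.  Query points are
// nudged by a sub-tolerance irrational offset so rays avoid mesh edges.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector contains_batch_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  int nf = F.nrow(), np = P.nrow();
  LogicalVector out(np);
  if (nf == 0) { std::fill(out.begin(), out.end(), false); return out; }

  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  std::vector<double> bx0(nf), bx1(nf), by0(nf), by1(nf), bz1(nf);
  for (int i = 0; i < nf; ++i) {
    int a = F(i,0)-1, b = F(i,1)-1, c = F(i,2)-1;
    bx0[i] = std::min({V(a,0), V(b,0), V(c,0)});
    bx1[i] = std::max({V(a,0), V(b,0), V(c,0)});
    by0[i] = std::min({V(a,1), V(b,1), V(c,1)});
    by1[i] = std::max({V(a,1), V(b,1), V(c,1)});
    bz1[i] = std::max({V(a,2), V(b,2), V(c,2)});
    xmin = std::min(xmin, bx0[i]); xmax = std::max(xmax, bx1[i]);
    ymin = std::min(ymin, by0[i]); ymax = std::max(ymax, by1[i]);
  }
  int G = (int)std::ceil(std::sqrt((double)nf / 8.0));
  G = std::max(8, std::min(G, 512));
  double gx = (xmax - xmin) / G, gy = (ymax - ymin) / G;
  if (gx <= 0) gx = 1.0; if (gy <= 0) gy = 1.0;

  // counting-sort faces into cells they overlap
  std::vector<int> count(G * G + 1, 0);
  auto cell_of = [&](double x, double y, int &cx, int &cy) {
    cx = (int)((x - xmin) / gx); cy = (int)((y - ymin) / gy);
    cx = std::max(0, std::min(G - 1, cx)); cy = std::max(0, std::min(G - 1, cy));
  };
  std::vector<int> c0x(nf), c0y(nf), c1x(nf), c1y(nf);
  for (int i = 0; i < nf; ++i) {
    cell_of(bx0[i], by0[i], c0x[i], c0y[i]);
    cell_of(bx1[i], by1[i], c1x[i], c1y[i]);
    for (int cy = c0y[i]; cy <= c1y[i]; ++cy)
      for (int cx = c0x[i]; cx <= c1x[i]; ++cx)
        count[cy * G + cx + 1]++;
  }
  for (int i = 0; i < G * G; ++i) count[i + 1] += count[i];
  std::vector<int> bucket(count[G * G]);
  std::vector<int> fill(count.begin(), count.end() - 1);
  for (int i = 0; i < nf; ++i)
    for (int cy = c0y[i]; cy <= c1y[i]; ++cy)
      for (int cx = c0x[i]; cx <= c1x[i]; ++cx)
        bucket[fill[cy * G + cx]++] = i;

  const double JX = 3.14159e-8, JY = 2.71828e-8; // edge-avoidance nudge
  for (int p = 0; p < np; ++p) {
    double px = P(p,0) + JX, py = P(p,1) + JY, pz = P(p,2);
    if (px < xmin || px > xmax || py < ymin || py > ymax) { out[p] = false; continue; }
    int cx, cy; cell_of(px, py, cx, cy);
    int lo = count[cy * G + cx], hi = count[cy * G + cx + 1];
    int crossings = 0;
    for (int k = lo; k < hi; ++k) {
      int i = bucket[k];
      if (px < bx0[i] || px > bx1[i] || py < by0[i] || py > by1[i] || bz1[i] < pz)
        continue;
      int a = F(i,0)-1, b = F(i,1)-1, c = F(i,2)-1;
      // 2D barycentric in the xy projection, then z of the hit
      double ax = V(a,0), ay = V(a,1), bx = V(b,0), byv = V(b,1), cxv = V(c,0), cyv = V(c,1);
      double d = (byv - cyv) * (ax - cxv) + (cxv - bx) * (ay - cyv);
      if (std::fabs(d) < 1e-14) continue;
      double l1 = ((byv - cyv) * (px - cxv) + (cxv - bx) * (py - cyv)) / d;
      double l2 = ((cyv - ay) * (px - cxv) + (ax - cxv) * (py - cyv)) / d;
      double l3 = 1.0 - l1 - l2;
      if (l1 < 0 || l2 < 0 || l3 < 0) continue;
      double zhit = l1 * V(a,2) + l2 * V(b,2) + l3 * V(c,2);
      if (zhit > pz) crossings++;
    }
    out[p] = (crossings % 2) == 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Minimum distance from each query point to the triangle soup (exact
// point-triangle distance, Eberly's region decomposition).
// ---------------------------------------------------------------------------

static double pt_tri_dist2(const double p[3], const double a[3],
                           const double b[3], const double c[3]) {
  double ab[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double ac[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double ap[3] = {p[0]-a[0], p[1]-a[1], p[2]-a[2]};
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  auto dist2_to = [&](double qx, double qy, double qz) {
    double dx = p[0]-qx, dy = p[1]-qy, dz = p[2]-qz;
    return dx*dx + dy*dy + dz*dz;
  };
  if (d1 <= 0 && d2 <= 0) return dist2_to(a[0], a[1], a[2]);
  double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) return dist2_to(b[0], b[1], b[2]);
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return dist2_to(a[0]+v*ab[0], a[1]+v*ab[1], a[2]+v*ab[2]);
  }
  double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) return dist2_to(c[0], c[1], c[2]);
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return dist2_to(a[0]+w*ac[0], a[1]+w*ac[1], a[2]+w*ac[2]);
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2_to(b[0]+w*(c[0]-b[0]), b[1]+w*(c[1]-b[1]), b[2]+w*(c[2]-b[2]));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return dist2_to(a[0]+ab[0]*v+ac[0]*w, a[1]+ab[1]*v+ac[1]*w, a[2]+ab[2]*v+ac[2]*w);
}

// [[Rcpp::export]]
NumericVector point_mesh_dist_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  int nf = F.nrow(), np = P.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double q[3] = {P(p,0), P(p,1), P(p,2)};
    double best = R_PosInf;
    for (int i = 0; i < nf; ++i) {
      int ia = F(i,0)-1, ib = F(i,1)-1, ic = F(i,2)-1;
      double a[3] = {V(ia,0), V(ia,1), V(ia,2)};
      double b[3] = {V(ib,0), V(ib,1), V(ib,2)};
      double c[3] = {V(ic,0), V(ic,1), V(ic,2)};
      double d2 = pt_tri_dist2(q, a, b, c);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
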