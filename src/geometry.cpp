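// Computational-geometry core: Voronoi tessellation of localization point
// clouds (2D cells, 3D cell volumes), polygon clipping against nuclear masks,
// clipped search-disk areas for radial density profiling, grid-accelerated
// single-linkage clustering and nearest-neighbour queries, and Gaussian
// rendering. All coordinates are nanometres.
//
// Masks may be non-convex simple polygons with polygonal exclusions
// (nucleoli). Voronoi cells are convex, so every mask operation reduces to
// Sutherland-Hodgman clipping of an arbitrary subject polygon against a
// convex clip region, plus shoelace areas; holes are handled by subtraction.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

struct Pt { double x, y; };

static inline double shoelace(const std::vector<Pt>& p) {
  const size_t n = p.size();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (size_t i = 0, j = n - 1; i < n; j = i++)
    a += (p[j].x * p[i].y - p[i].x * p[j].y);
  return 0.5 * a;
}

static std::vector<Pt> mat_to_poly(const NumericMatrix& m) {
  std::vector<Pt> p(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) p[i] = {m(i, 0), m(i, 1)};
  return p;
}

static NumericMatrix poly_to_mat(const std::vector<Pt>& p) {
  NumericMatrix m(p.size(), 2);
  for (size_t i = 0; i < p.size(); ++i) { m(i, 0) = p[i].x; m(i, 1) = p[i].y; }
  return m;
}

// Clip polygon (any winding, any convexity) against half-plane n.x <= d.
// Subject need not be convex; output area via shoelace stays exact.
static void clip_halfplane(std::vector<Pt>& poly, double nx, double ny, double d,
                           std::vector<Pt>& out) {
  out.clear();
  const size_t n = poly.size();
  if (n == 0) return;
  double sprev = nx * poly[n - 1].x + ny * poly[n - 1].y - d;
  for (size_t i = 0; i < n; ++i) {
    double scur = nx * poly[i].x + ny * poly[i].y - d;
    const Pt& prev = poly[(i + n - 1) % n];
    if (scur <= 0) {
      if (sprev > 0) {
        double t = sprev / (sprev - scur);
        out.push_back({prev.x + t * (poly[i].x - prev.x),
                       prev.y + t * (poly[i].y - prev.y)});
      }
      out.push_back(poly[i]);
    } else if (sprev <= 0) {
      double t = sprev / (sprev - scur);
      out.push_back({prev.x + t * (poly[i].x - prev.x),
                     prev.y + t * (poly[i].y - prev.y)});
    }
    sprev = scur;
  }
}

// Sutherland-Hodgman: subject (arbitrary simple polygon) against convex clip
// polygon given in CCW order.
static std::vector<Pt> clip_convex(const std::vector<Pt>& subject,
                                   const std::vector<Pt>& clip) {
  std::vector<Pt> cur = subject, next;
  const size_t m = clip.size();
  for (size_t e = 0; e < m && !cur.empty(); ++e) {
    const Pt& a = clip[e];
    const Pt& b = clip[(e + 1) % m];
    // CCW clip: interior is left of (a,b); outward normal points right
    double nx = b.y - a.y, ny = -(b.x - a.x);
    double d = nx * a.x + ny * a.y;
    clip_halfplane(cur, nx, ny, d, next);
    cur.swap(next);
  }
  return cur;
}

// Area of (convex CCW cell) intersect usable mask = boundary minus exclusions.
static double masked_area(const std::vector<Pt>& cell,
                          const std::vector<std::vector<Pt>>& boundary_and_excl) {
  // element 0 = boundary (CCW), rest = exclusions (CCW); subtract holes
  double a = std::fabs(shoelace(clip_convex(boundary_and_excl[0], cell)));
  for (size_t k = 1; k < boundary_and_excl.size(); ++k)
    a -= std::fabs(shoelace(clip_convex(boundary_and_excl[k], cell)));
  return a;
}

// ---------------------------------------------------------------------------
// exported basics
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_polygon_area(NumericMatrix poly) {
  std::vector<Pt> p = mat_to_poly(poly);
  return shoelace(p);
}

// Even-odd point-in-polygon with boundary tolerance tol (points within tol of
// an edge count as inside).
// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericVector px, NumericVector py,
                                    NumericMatrix poly, double tol) {
  std::vector<Pt> P = mat_to_poly(poly);
  const size_t m = P.size(), n = px.size();
  LogicalVector res(n);
  for (size_t i = 0; i < n; ++i) {
    double x = px[i], y = py[i];
    bool inside = false, onb = false;
    for (size_t j = 0, k = m - 1; j < m; k = j++) {
      double x1 = P[k].x, y1 = P[k].y, x2 = P[j].x, y2 = P[j].y;
      // distance to segment
      double dx = x2 - x1, dy = y2 - y1;
      double L2 = dx * dx + dy * dy;
      double t = L2 > 0 ? ((x - x1) * dx + (y - y1) * dy) / L2 : 0.0;
      t = std::max(0.0, std::min(1.0, t));
      double ddx = x - (x1 + t * dx), ddy = y - (y1 + t * dy);
      if (ddx * ddx + ddy * ddy <= tol * tol) { onb = true; break; }
      if (((y1 > y) != (y2 > y)) &&
          (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1))
        inside = !inside;
    }
    res[i] = inside || onb;
  }
  return res;
}

// Minimum distance from each point to the polygon outline.
// [[Rcpp::export]]
NumericVector cpp_dist_to_polygon(NumericVector px, NumericVector py,
                                  NumericMatrix poly) {
  std::vector<Pt> P = mat_to_poly(poly);
  const size_t m = P.size(), n = px.size();
  NumericVector res(n);
  for (size_t i = 0; i < n; ++i) {
    double x = px[i], y = py[i], best = std::numeric_limits<double>::infinity();
    for (size_t j = 0, k = m - 1; j < m; k = j++) {
      double x1 = P[k].x, y1 = P[k].y, dx = P[j].x - x1, dy = P[j].y - y1;
      double L2 = dx * dx + dy * dy;
      double t = L2 > 0 ? ((x - x1) * dx + (y - y1) * dy) / L2 : 0.0;
      t = std::max(0.0, std::min(1.0, t));
      double ddx = x - (x1 + t * dx), ddy = y - (y1 + t * dy);
      best = std::min(best, ddx * ddx + ddy * ddy);
    }
    res[i] = std::sqrt(best);
  }
  return res;
}

// Intersection area of an arbitrary simple polygon with a convex CCW polygon.
// [[Rcpp::export]]
double cpp_convex_clip_area(NumericMatrix subject, NumericMatrix clip) {
  std::vector<Pt> out = clip_convex(mat_to_poly(subject), mat_to_poly(clip));
  return std::fabs(shoelace(out));
}

// [[Rcpp::export]]
NumericMatrix cpp_convex_clip(NumericMatrix subject, NumericMatrix clip) {
  return poly_to_mat(clip_convex(mat_to_poly(subject), mat_to_poly(clip)));
}

// ---------------------------------------------------------------------------
// 2D Voronoi by half-plane clipping with grid-accelerated security radius
// ---------------------------------------------------------------------------

struct Grid2 {
  double x0, y0, hx, hy;
  int nx, ny;
  std::vector<std::vector<int>> buckets;
  Grid2(const NumericVector& x, const NumericVector& y,
        double xlo, double xhi, double ylo, double yhi) {
    const int n = x.size();
    double W = std::max(xhi - xlo, 1e-9), H = std::max(yhi - ylo, 1e-9);
    double h = std::sqrt(W * H / std::max(n, 1));
    nx = std::max(1, (int)std::ceil(W / h));
    ny = std::max(1, (int)std::ceil(H / h));
    nx = std::min(nx, 2048); ny = std::min(ny, 2048);
    x0 = xlo; y0 = ylo; hx = W / nx; hy = H / ny;
    buckets.assign((size_t)nx * ny, {});
    for (int i = 0; i < n; ++i) buckets[cell_of(x[i], y[i])].push_back(i);
  }
  size_t cell_of(double x, double y) const {
    int ix = std::min(nx - 1, std::max(0, (int)((x - x0) / hx)));
    int iy = std::min(ny - 1, std::max(0, (int)((y - y0) / hy)));
    return (size_t)iy * nx + ix;
  }
  void ring(double x, double y, int k, std::vector<int>& out) const {
    int cx = std::min(nx - 1, std::max(0, (int)((x - x0) / hx)));
    int cy = std::min(ny - 1, std::max(0, (int)((y - y0) / hy)));
    for (int iy = cy - k; iy <= cy + k; ++iy) {
      if (iy < 0 || iy >= ny) continue;
      for (int ix = cx - k; ix <= cx + k; ++ix) {
        if (ix < 0 || ix >= nx) continue;
        if (std::max(std::abs(ix - cx), std::abs(iy - cy)) != k) continue;
        const auto& b = buckets[(size_t)iy * nx + ix];
        out.insert(out.end(), b.begin(), b.end());
      }
    }
  }
  int max_rings() const { return std::max(nx, ny); }
  double hmin() const { return std::min(hx, hy); }
};

// Voronoi cells of (x, y), clipped to the axis-aligned rectangle
// [xlo,xhi] x [ylo,yhi]. Returns one CCW convex polygon per seed.
// Callers must de-duplicate seeds beforehand (deterministic jitter in R).
// [[Rcpp::export]]
List cpp_voronoi2d(NumericVector x, NumericVector y,
                   double xlo, double xhi, double ylo, double yhi) {
  const int n = x.size();
  Grid2 grid(x, y, xlo, xhi, ylo, yhi);
  List cells(n);
  std::vector<Pt> cell, next;
  std::vector<std::pair<double, int>> pending;
  std::vector<int> ringbuf;
  for (int i = 0; i < n; ++i) {
    cell = {{xlo, ylo}, {xhi, ylo}, {xhi, yhi}, {xlo, yhi}};
    double px = x[i], py = y[i];
    auto maxR2 = [&]() {
      double r2 = 0;
      for (const Pt& v : cell) {
        double dx = v.x - px, dy = v.y - py;
        r2 = std::max(r2, dx * dx + dy * dy);
      }
      return r2;
    };
    double R2 = maxR2();
    pending.clear();
    int k = 0;
    const int kmax = grid.max_rings();
    while (true) {
      ringbuf.clear();
      if (k <= kmax) grid.ring(px, py, k, ringbuf);
      for (int j : ringbuf) {
        if (j == i) continue;
        double dx = x[j] - px, dy = y[j] - py;
        pending.push_back({dx * dx + dy * dy, j});
      }
      std::sort(pending.begin(), pending.end());
      size_t used = 0;
      for (; used < pending.size(); ++used) {
        if (pending[used].first > 4.0 * R2) break;  // d > 2R cannot cut
        int j = pending[used].second;
        double nxv = x[j] - px, nyv = y[j] - py;
        double d = nxv * 0.5 * (x[j] + px) + nyv * 0.5 * (y[j] + py);
        clip_halfplane(cell, nxv, nyv, d, next);
        cell.swap(next);
        if (cell.empty()) break;
        R2 = maxR2();
      }
      pending.erase(pending.begin(), pending.begin() + used);
      if (cell.empty()) break;
      // all unseen seeds are at distance >= (k) * hmin - diag; safe bound
      double bound = (k - 1) * grid.hmin();
      if ((bound > 0 && bound * bound > 4.0 * R2) || k > kmax) break;
      ++k;
    }
    cells[i] = poly_to_mat(cell);
  }
  return cells;
}

// Per-cell area after clipping to a mask (boundary polygon minus exclusion
// polygons, all CCW). cells: list of convex CCW polygons.
// [[Rcpp::export]]
NumericVector cpp_masked_areas(List cells, List mask_polys) {
  std::vector<std::vector<Pt>> mp;
  for (int k = 0; k < mask_polys.size(); ++k)
    mp.push_back(mat_to_poly(mask_polys[k]));
  NumericVector out(cells.size());
  for (int i = 0; i < cells.size(); ++i) {
    NumericMatrix cm = cells[i];
    if (cm.nrow() < 3) { out[i] = 0.0; continue; }
    out[i] = masked_area(mat_to_poly(cm), mp);
  }
  return out;
}

// ---------------------------------------------------------------------------
// clipped search-disk areas for radial profiling
// ---------------------------------------------------------------------------

// For each clutch cell (convex CCW Voronoi polygon of the clutch centroid,
// already clipped to the mask bounding box), compute the area of
// disk(centroid, r) n cell n mask for each radius. Disks are polygonized with
// nvert vertices (area error < 0.1% at nvert >= 64; default callers use 128).
// dist_to_mask: precomputed distance from each centroid to the nearest mask
// outline (boundary or exclusion); if r + eps < dist the mask clip is skipped.
// [[Rcpp::export]]
NumericMatrix cpp_clipped_disk_areas(List cells, NumericVector cx, NumericVector cy,
                                     NumericVector radii, List mask_polys,
                                     NumericVector dist_to_mask, int nvert) {
  const int n = cells.size(), nr = radii.size();
  std::vector<std::vector<Pt>> mp;
  for (int k = 0; k < mask_polys.size(); ++k)
    mp.push_back(mat_to_poly(mask_polys[k]));
  // unit circle template
  std::vector<Pt> unit(nvert);
  for (int v = 0; v < nvert; ++v) {
    double a = 2.0 * M_PI * v / nvert;
    unit[v] = {std::cos(a), std::sin(a)};
  }
  NumericMatrix out(n, nr);
  std::vector<Pt> circ(nvert);
  for (int i = 0; i < n; ++i) {
    NumericMatrix cm = cells[i];
    std::vector<Pt> cell = mat_to_poly(cm);
    if (cell.size() < 3) { for (int r = 0; r < nr; ++r) out(i, r) = 0.0; continue; }
    // max distance from centroid to cell vertex: beyond that the disk covers
    // the whole cell and the area saturates
    double vmax2 = 0;
    for (const Pt& v : cell) {
      double dx = v.x - cx[i], dy = v.y - cy[i];
      vmax2 = std::max(vmax2, dx * dx + dy * dy);
    }
    double cell_mask_area = -1.0;
    for (int r = 0; r < nr; ++r) {
      double rad = radii[r];
      bool covers_cell = rad * rad >= vmax2;
      if (covers_cell) {
        if (cell_mask_area < 0) cell_mask_area = masked_area(cell, mp);
        out(i, r) = cell_mask_area;
        continue;
      }
      for (int v = 0; v < nvert; ++v)
        circ[v] = {cx[i] + rad * unit[v].x, cy[i] + rad * unit[v].y};
      std::vector<Pt> dc = clip_convex(circ, cell);
      if (rad < dist_to_mask[i]) {
        out(i, r) = std::fabs(shoelace(dc));       // mask cannot intersect
      } else if (dc.size() >= 3) {
        out(i, r) = masked_area(dc, mp);           // dc is convex (circle n cell)
      } else {
        out(i, r) = 0.0;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D Voronoi volumes clipped to the mask prism
// ---------------------------------------------------------------------------

struct V3 { double x, y, z; };
struct Poly3 {
  std::vector<V3> verts;
  std::vector<std::vector<int>> faces;  // outward-oriented vertex loops
};

static Poly3 make_box(double xlo, double xhi, double ylo, double yhi,
                      double zlo, double zhi) {
  Poly3 p;
  p.verts = {{xlo, ylo, zlo}, {xhi, ylo, zlo}, {xhi, yhi, zlo}, {xlo, yhi, zlo},
             {xlo, ylo, zhi}, {xhi, ylo, zhi}, {xhi, yhi, zhi}, {xlo, yhi, zhi}};
  p.faces = {{0, 3, 2, 1},   // bottom (outward -z)
             {4, 5, 6, 7},   // top (+z)
             {0, 1, 5, 4},   // -y
             {2, 3, 7, 6},   // +y
             {1, 2, 6, 5},   // +x
             {0, 4, 7, 3}};  // -x
  return p;
}

static double poly3_volume(const Poly3& p) {
  double v6 = 0;
  for (const auto& f : p.faces) {
    for (size_t i = 1; i + 1 < f.size(); ++i) {
      const V3& a = p.verts[f[0]];
      const V3& b = p.verts[f[i]];
      const V3& c = p.verts[f[i + 1]];
      v6 += a.x * (b.y * c.z - b.z * c.y)
          - a.y * (b.x * c.z - b.z * c.x)
          + a.z * (b.x * c.y - b.y * c.x);
    }
  }
  return std::fabs(v6) / 6.0;
}

// Clip convex polyhedron by half-space n.x <= d. Returns false if empty.
static bool poly3_clip(Poly3& p, double nx, double ny, double nz, double d,
                       double eps) {
  const size_t nv = p.verts.size();
  if (nv == 0) return false;
  std::vector<double> side(nv);
  int npos = 0, nneg = 0;
  for (size_t i = 0; i < nv; ++i) {
    side[i] = nx * p.verts[i].x + ny * p.verts[i].y + nz * p.verts[i].z - d;
    if (side[i] > eps) ++npos; else if (side[i] < -eps) ++nneg;
  }
  if (npos == 0) return true;              // fully inside
  if (nneg == 0) { p.verts.clear(); p.faces.clear(); return false; }
  Poly3 q;
  std::vector<V3> cap_pts;
  auto push_vert = [&](const V3& v) {
    q.verts.push_back(v);
    return (int)q.verts.size() - 1;
  };
  // map old vertex -> new index (only for kept verts)
  std::vector<int> keep(nv, -1);
  for (size_t i = 0; i < nv; ++i)
    if (side[i] <= eps) keep[i] = push_vert(p.verts[i]);
  for (const auto& f : p.faces) {
    std::vector<int> nf;
    const size_t m = f.size();
    for (size_t i = 0; i < m; ++i) {
      int a = f[i], b = f[(i + 1) % m];
      bool ain = side[a] <= eps, bin = side[b] <= eps;
      if (ain) nf.push_back(keep[a]);
      if (ain != bin) {
        double t = side[a] / (side[a] - side[b]);
        V3 ip = {p.verts[a].x + t * (p.verts[b].x - p.verts[a].x),
                 p.verts[a].y + t * (p.verts[b].y - p.verts[a].y),
                 p.verts[a].z + t * (p.verts[b].z - p.verts[a].z)};
        int idx = push_vert(ip);
        nf.push_back(idx);
        cap_pts.push_back(ip);
      }
    }
    if (nf.size() >= 3) q.faces.push_back(nf);
  }
  // cap face: convex loop on the plane; order by angle around centroid and
  // orient so the outward normal is +n
  if (cap_pts.size() >= 3) {
    V3 c = {0, 0, 0};
    for (const V3& v : cap_pts) { c.x += v.x; c.y += v.y; c.z += v.z; }
    double inv = 1.0 / cap_pts.size();
    c = {c.x * inv, c.y * inv, c.z * inv};
    // basis in the plane
    double ax = std::fabs(nx), ay = std::fabs(ny), az = std::fabs(nz);
    V3 ref = ax <= ay && ax <= az ? V3{1, 0, 0} : (ay <= az ? V3{0, 1, 0} : V3{0, 0, 1});
    V3 u = {ny * ref.z - nz * ref.y, nz * ref.x - nx * ref.z, nx * ref.y - ny * ref.x};
    double ul = std::sqrt(u.x * u.x + u.y * u.y + u.z * u.z);
    u = {u.x / ul, u.y / ul, u.z / ul};
    V3 w = {ny * u.z - nz * u.y, nz * u.x - nx * u.z, nx * u.y - ny * u.x};
    std::vector<std::pair<double, V3>> ang;
    for (const V3& v : cap_pts) {
      V3 dv = {v.x - c.x, v.y - c.y, v.z - c.z};
      ang.push_back({std::atan2(dv.x * w.x + dv.y * w.y + dv.z * w.z,
                                dv.x * u.x + dv.y * u.y + dv.z * u.z), v});
    }
    std::sort(ang.begin(), ang.end(),
              [](const std::pair<double, V3>& A, const std::pair<double, V3>& B) {
                return A.first < B.first;
              });
    std::vector<int> cap;
    double tol2 = eps * eps * 100.0 + 1e-18;
    for (auto& pr : ang) {
      if (!cap.empty()) {
        const V3& prev = q.verts[cap.back()];
        double dx = pr.second.x - prev.x, dy = pr.second.y - prev.y,
               dz = pr.second.z - prev.z;
        if (dx * dx + dy * dy + dz * dz < tol2) continue;
      }
      cap.push_back(push_vert(pr.second));
    }
    if (cap.size() >= 3) {
      // (u,w,n) is a right-handed frame iff u x w = n... u x w = -n for
      // w = n x u, so CCW-in-(u,w) loops have outward normal -n; since
      // w = n x u gives u x w = u x (n x u) = n (|u|=1, u.n=0), the loop
      // sorted by atan2(w, u) is CCW about +n; outward cap normal must be +n,
      // which matches.
      q.faces.push_back(cap);
    }
  }
  p = std::move(q);
  return !p.faces.empty();
}

struct Grid3 {
  double x0, y0, z0, hx, hy, hz;
  int nx, ny, nz;
  std::vector<std::vector<int>> buckets;
  Grid3(const NumericVector& x, const NumericVector& y, const NumericVector& z,
        double xlo, double xhi, double ylo, double yhi, double zlo, double zhi) {
    const int n = x.size();
    double W = std::max(xhi - xlo, 1e-9), H = std::max(yhi - ylo, 1e-9),
           D = std::max(zhi - zlo, 1e-9);
    double h = std::cbrt(W * H * D / std::max(n, 1));
    nx = std::min(256, std::max(1, (int)std::ceil(W / h)));
    ny = std::min(256, std::max(1, (int)std::ceil(H / h)));
    nz = std::min(64, std::max(1, (int)std::ceil(D / h)));
    x0 = xlo; y0 = ylo; z0 = zlo;
    hx = W / nx; hy = H / ny; hz = D / nz;
    buckets.assign((size_t)nx * ny * nz, {});
    for (int i = 0; i < n; ++i) {
      int ix = std::min(nx - 1, std::max(0, (int)((x[i] - x0) / hx)));
      int iy = std::min(ny - 1, std::max(0, (int)((y[i] - y0) / hy)));
      int iz = std::min(nz - 1, std::max(0, (int)((z[i] - z0) / hz)));
      buckets[((size_t)iz * ny + iy) * nx + ix].push_back(i);
    }
  }
  void shell(double x, double y, double z, int k, std::vector<int>& out) const {
    int cx = std::min(nx - 1, std::max(0, (int)((x - x0) / hx)));
    int cy = std::min(ny - 1, std::max(0, (int)((y - y0) / hy)));
    int cz = std::min(nz - 1, std::max(0, (int)((z - z0) / hz)));
    for (int iz = cz - k; iz <= cz + k; ++iz) {
      if (iz < 0 || iz >= nz) continue;
      for (int iy = cy - k; iy <= cy + k; ++iy) {
        if (iy < 0 || iy >= ny) continue;
        for (int ix = cx - k; ix <= cx + k; ++ix) {
          if (ix < 0 || ix >= nx) continue;
          int cheb = std::max(std::abs(ix - cx),
                              std::max(std::abs(iy - cy), std::abs(iz - cz)));
          if (cheb != k) continue;
          const auto& b = buckets[((size_t)iz * ny + iy) * nx + ix];
          out.insert(out.end(), b.begin(), b.end());
        }
      }
    }
  }
  int max_shells() const { return std::max(nx, std::max(ny, nz)); }
  double hmin() const { return std::min(hx, std::min(hy, hz)); }
};

// Volumes of 3D Voronoi cells clipped to the prism (mask polygon x z-slab).
// mask_polys: boundary (index 0, CCW) + exclusions (CCW). Uses a signed fan
// triangulation of each mask polygon so non-convex boundaries are exact.
// [[Rcpp::export]]
NumericVector cpp_voronoi3d_volumes(NumericVector x, NumericVector y, NumericVector z,
                                    List mask_polys, double zlo, double zhi) {
  const int n = x.size();
  NumericMatrix bnd = mask_polys[0];
  double xlo = bnd(0, 0), xhi = bnd(0, 0), ylo = bnd(0, 1), yhi = bnd(0, 1);
  for (int i = 0; i < bnd.nrow(); ++i) {
    xlo = std::min(xlo, bnd(i, 0)); xhi = std::max(xhi, bnd(i, 0));
    ylo = std::min(ylo, bnd(i, 1)); yhi = std::max(yhi, bnd(i, 1));
  }
  const double scale = std::max({xhi - xlo, yhi - ylo, zhi - zlo});
  const double eps = 1e-9 * scale;
  Grid3 grid(x, y, z, xlo, xhi, ylo, yhi, zlo, zhi);
  // fan triangulations (signed) of each mask polygon
  struct Tri { Pt a, b, c; double sign; };
  std::vector<std::vector<Tri>> fans;
  std::vector<std::vector<Pt>> mp;
  for (int k = 0; k < mask_polys.size(); ++k) {
    std::vector<Pt> poly = mat_to_poly(mask_polys[k]);
    mp.push_back(poly);
    std::vector<Tri> fan;
    for (size_t i = 1; i + 1 < poly.size(); ++i) {
      Tri t = {poly[0], poly[i], poly[i + 1], 0.0};
      double a2 = (t.b.x - t.a.x) * (t.c.y - t.a.y)
                - (t.c.x - t.a.x) * (t.b.y - t.a.y);
      if (std::fabs(a2) < 1e-12) continue;
      t.sign = a2 > 0 ? 1.0 : -1.0;
      fan.push_back(t);
    }
    fans.push_back(fan);
  }
  auto tri_prism_volume = [&](const Poly3& cell, const Tri& t) {
    // clip by the 3 vertical planes of the (possibly CW) triangle, oriented
    // so the interior is kept
    Pt A = t.a, B = t.b, C = t.c;
    if (t.sign < 0) std::swap(B, C);  // make CCW
    Poly3 q = cell;
    Pt tri[3] = {A, B, C};
    for (int e = 0; e < 3; ++e) {
      Pt p1 = tri[e], p2 = tri[(e + 1) % 3];
      double nx = p2.y - p1.y, ny = -(p2.x - p1.x);  // outward for CCW
      double d = nx * p1.x + ny * p1.y;
      if (!poly3_clip(q, nx, ny, 0.0, d, eps)) return 0.0;
    }
    return poly3_volume(q);
  };
  NumericVector vols(n);
  std::vector<std::pair<double, int>> pending;
  std::vector<int> shellbuf;
  for (int i = 0; i < n; ++i) {
    Poly3 cell = make_box(xlo, xhi, ylo, yhi, zlo, zhi);
    double px = x[i], py = y[i], pz = z[i];
    auto maxR2 = [&]() {
      double r2 = 0;
      for (const V3& v : cell.verts) {
        double dx = v.x - px, dy = v.y - py, dz = v.z - pz;
        r2 = std::max(r2, dx * dx + dy * dy + dz * dz);
      }
      return r2;
    };
    double R2 = maxR2();
    pending.clear();
    int k = 0;
    const int kmax = grid.max_shells();
    bool alive = true;
    while (alive) {
      shellbuf.clear();
      if (k <= kmax) grid.shell(px, py, pz, k, shellbuf);
      for (int j : shellbuf) {
        if (j == i) continue;
        double dx = x[j] - px, dy = y[j] - py, dz = z[j] - pz;
        pending.push_back({dx * dx + dy * dy + dz * dz, j});
      }
      std::sort(pending.begin(), pending.end());
      size_t used = 0;
      for (; used < pending.size(); ++used) {
        if (pending[used].first > 4.0 * R2) break;
        int j = pending[used].second;
        double nxv = x[j] - px, nyv = y[j] - py, nzv = z[j] - pz;
        double d = nxv * 0.5 * (x[j] + px) + nyv * 0.5 * (y[j] + py)
                 + nzv * 0.5 * (z[j] + pz);
        if (!poly3_clip(cell, nxv, nyv, nzv, d, eps)) { alive = false; break; }
        R2 = maxR2();
      }
      pending.erase(pending.begin(), pending.begin() + std::min(used, pending.size()));
      if (!alive) break;
      double bound = (k - 1) * grid.hmin();
      if ((bound > 0 && bound * bound > 4.0 * R2) || k > kmax) break;
      ++k;
    }
    if (!alive || cell.faces.empty()) { vols[i] = 0.0; continue; }
    // fast path: cell xy-bbox strictly inside boundary and away from exclusions
    double bxlo = cell.verts[0].x, bxhi = bxlo, bylo = cell.verts[0].y, byhi = bylo;
    for (const V3& v : cell.verts) {
      bxlo = std::min(bxlo, v.x); bxhi = std::max(bxhi, v.x);
      bylo = std::min(bylo, v.y); byhi = std::max(byhi, v.y);
    }
    double cxm = 0.5 * (bxlo + bxhi), cym = 0.5 * (bylo + byhi);
    double brad = std::sqrt((bxhi - cxm) * (bxhi - cxm) + (byhi - cym) * (byhi - cym));
    bool interior = true;
    for (size_t m = 0; m < mp.size() && interior; ++m) {
      const std::vector<Pt>& P = mp[m];
      double best = std::numeric_limits<double>::infinity();
      for (size_t a = 0, b = P.size() - 1; a < P.size(); b = a++) {
        double x1 = P[b].x, y1 = P[b].y, dx = P[a].x - x1, dy = P[a].y - y1;
        double L2 = dx * dx + dy * dy;
        double t = L2 > 0 ? ((cxm - x1) * dx + (cym - y1) * dy) / L2 : 0.0;
        t = std::max(0.0, std::min(1.0, t));
        double ddx = cxm - (x1 + t * dx), ddy = cym - (y1 + t * dy);
        best = std::min(best, ddx * ddx + ddy * ddy);
      }
      if (best <= brad * brad * 1.0201) interior = false;  // 1% margin
    }
    if (interior) { vols[i] = poly3_volume(cell); continue; }
    double v = 0.0;
    for (const Tri& t : fans[0]) v += t.sign * tri_prism_volume(cell, t);
    for (size_t m = 1; m < fans.size(); ++m)
      for (const Tri& t : fans[m]) v -= t.sign * tri_prism_volume(cell, t);
    vols[i] = std::max(v, 0.0);
  }
  return vols;
}

// ---------------------------------------------------------------------------
// clustering / neighbour queries
// ---------------------------------------------------------------------------

struct UnionFind {
  std::vector<int> parent, rank_;
  UnionFind(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
  }
};

// Single-linkage connected components of the <= eps distance graph.
// Returns 1-based component labels in first-appearance order.
// [[Rcpp::export]]
IntegerVector cpp_single_linkage(NumericVector x, NumericVector y, double eps) {
  const int n = x.size();
  IntegerVector lab(n);
  if (n == 0) return lab;
  double xlo = x[0], xhi = x[0], ylo = y[0], yhi = y[0];
  for (int i = 0; i < n; ++i) {
    xlo = std::min(xlo, x[i]); xhi = std::max(xhi, x[i]);
    ylo = std::min(ylo, y[i]); yhi = std::max(yhi, y[i]);
  }
  // grid with cell size eps: neighbours live in the 3x3 block
  double W = std::max(xhi - xlo, eps), H = std::max(yhi - ylo, eps);
  int nx = std::min(4096, std::max(1, (int)std::ceil(W / eps)));
  int ny = std::min(4096, std::max(1, (int)std::ceil(H / eps)));
  double hx = W / nx, hy = H / ny;
  // guarantee cell size >= eps so 3x3 blocks suffice
  if (hx < eps) { nx = std::max(1, (int)(W / eps)); hx = W / nx; }
  if (hy < eps) { ny = std::max(1, (int)(H / eps)); hy = H / ny; }
  std::vector<std::vector<int>> buckets((size_t)nx * ny);
  auto cell_ix = [&](double v, double lo, double h, int nmax) {
    return std::min(nmax - 1, std::max(0, (int)((v - lo) / h)));
  };
  for (int i = 0; i < n; ++i)
    buckets[(size_t)cell_ix(y[i], ylo, hy, ny) * nx + cell_ix(x[i], xlo, hx, nx)]
        .push_back(i);
  UnionFind uf(n);
  const double eps2 = eps * eps;
  for (int i = 0; i < n; ++i) {
    int cx = cell_ix(x[i], xlo, hx, nx), cy = cell_ix(y[i], ylo, hy, ny);
    for (int iy = std::max(0, cy - 1); iy <= std::min(ny - 1, cy + 1); ++iy)
      for (int ix = std::max(0, cx - 1); ix <= std::min(nx - 1, cx + 1); ++ix)
        for (int j : buckets[(size_t)iy * nx + ix]) {
          if (j <= i) continue;
          double dx = x[i] - x[j], dy = y[i] - y[j];
          if (dx * dx + dy * dy <= eps2) uf.unite(i, j);
        }
  }
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (remap[r] == 0) remap[r] = ++next;
    lab[i] = remap[r];
  }
  return lab;
}

// Nearest neighbour (excluding self) for each point; brute force O(n^2).
// [[Rcpp::export]]
List cpp_nearest_neighbor(NumericVector x, NumericVector y) {
  const int n = x.size();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bj = NA_INTEGER;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bj = j + 1; }
    }
    idx[i] = bj;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Index (1-based) of the nearest seed for each query point; distance ties
// resolved in favour of the lowest seed index (strict < comparison over seeds
// scanned in increasing index order within candidate sets).
// [[Rcpp::export]]
IntegerVector cpp_assign_nearest(NumericVector px, NumericVector py,
                                 NumericVector sx, NumericVector sy) {
  const int np = px.size(), ns = sx.size();
  IntegerVector out(np);
  if (ns == 0) return out;
  double xlo = sx[0], xhi = sx[0], ylo = sy[0], yhi = sy[0];
  for (int i = 0; i < ns; ++i) {
    xlo = std::min(xlo, sx[i]); xhi = std::max(xhi, sx[i]);
    ylo = std::min(ylo, sy[i]); yhi = std::max(yhi, sy[i]);
  }
  Grid2 grid(sx, sy, xlo, xhi, ylo, yhi);
  std::vector<int> buf;
  for (int i = 0; i < np; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bj = NA_INTEGER;
    int kmax = grid.max_rings();
    for (int k = 0; k <= kmax; ++k) {
      buf.clear();
      grid.ring(px[i], py[i], k, buf);
      std::sort(buf.begin(), buf.end());
      for (int j : buf) {
        double dx = px[i] - sx[j], dy = py[i] - sy[j];
        double d2 = dx * dx + dy * dy;
        if (d2 < best) { best = d2; bj = j + 1; }
      }
      // all seeds in shells > k are at least (k) * hmin - hdiag away; stop
      // once that bound exceeds the best distance found
      double bound = (k - 1) * grid.hmin();
      if (bj != NA_INTEGER && bound > 0 && bound * bound > best) break;
    }
    out[i] = bj;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Gaussian rendering
// ---------------------------------------------------------------------------

// Sum of unit-mass isotropic Gaussians discretized by pixel-integrated mass
// (difference of error functions), truncated at 5 sigma.
// [[Rcpp::export]]
NumericMatrix cpp_render_gaussian(NumericVector x, NumericVector y, double sigma,
                                  double pixel, double x0, double y0,
                                  int nx, int ny) {
  NumericMatrix img(ny, nx);  // row = y index, col = x index
  const double s = sigma * std::sqrt(2.0);
  const int halo = (int)std::ceil(6.0 * sigma / pixel) + 1;
  const int n = x.size();
  std::vector<double> ex(2 * halo + 2), ey(2 * halo + 2);
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor((x[i] - x0) / pixel);
    int cy = (int)std::floor((y[i] - y0) / pixel);
    int ix0 = std::max(0, cx - halo), ix1 = std::min(nx - 1, cx + halo);
    int iy0 = std::max(0, cy - halo), iy1 = std::min(ny - 1, cy + halo);
    if (ix0 > ix1 || iy0 > iy1) continue;
    for (int ix = ix0; ix <= ix1 + 1; ++ix)
      ex[ix - ix0] = std::erf((x0 + ix * pixel - x[i]) / s);
    for (int iy = iy0; iy <= iy1 + 1; ++iy)
      ey[iy - iy0] = std::erf((y0 + iy * pixel - y[i]) / s);
    for (int iy = iy0; iy <= iy1; ++iy) {
      double wy = 0.5 * (ey[iy - iy0 + 1] - ey[iy - iy0]);
      for (int ix = ix0; ix <= ix1; ++ix)
        img(iy, ix) += wy * 0.5 * (ex[ix - ix0 + 1] - ex[ix - ix0]);
    }
  }
  return img;
}

// 2D occupancy histogram count (number of non-empty bins) on a grid anchored
// at (x0, y0) with square bins of size h.
// [[Rcpp::export]]
double cpp_occupied_bins(NumericVector x, NumericVector y, double x0, double y0,
                         double h, int nx, int ny) {
  std::vector<bool> occ((size_t)nx * ny, false);
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor((x[i] - x0) / h);
    int iy = (int)std::floor((y[i] - y0) / h);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) continue;
    occ[(size_t)iy * nx + ix] = true;
  }
  double cnt = 0;
  for (bool b : occ) if (b) ++cnt;
  return cnt;
}
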