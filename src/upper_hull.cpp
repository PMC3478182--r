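// 3D convex hull (incremental, horizon-based) and upper-envelope rasterization.
//
// The clean-surface reconstruction needs the *upper* facets of the convex hull
// of the point cloud {(x, y, brightness)}: a piecewise-linear concave surface
// that dominates every sample, whose planar interpolation fills dark (lesion)
// regions from the surrounding sound enamel.  Degenerate inputs (collinear
// (x, y) footprints, fully coplanar clouds) are resolved on the R side before
// this kernel is called.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Face {
  int a, b, c;            // vertex indices, oriented so the unit normal points outward
  double nx, ny, nz, off; // unit normal and plane offset: n . p == off on the face
  bool alive;
};

struct HullBuilder {
  const std::vector<double>& X;
  const std::vector<double>& Y;
  const std::vector<double>& Z;
  std::vector<Face> faces;
  double cx, cy, cz;      // interior reference point (centroid of seed tetrahedron)
  double eps;             // visibility tolerance on unit-normal distances

  HullBuilder(const std::vector<double>& x,
              const std::vector<double>& y,
              const std::vector<double>& z)
    : X(x), Y(y), Z(z), cx(0), cy(0), cz(0), eps(0) {}

  void plane(Face& f) const {
    double ux = X[f.b] - X[f.a], uy = Y[f.b] - Y[f.a], uz = Z[f.b] - Z[f.a];
    double vx = X[f.c] - X[f.a], vy = Y[f.c] - Y[f.a], vz = Z[f.c] - Z[f.a];
    f.nx = uy * vz - uz * vy;
    f.ny = uz * vx - ux * vz;
    f.nz = ux * vy - uy * vx;
    double len = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
    if (len > 0) { f.nx /= len; f.ny /= len; f.nz /= len; }
    f.off = f.nx * X[f.a] + f.ny * Y[f.a] + f.nz * Z[f.a];
  }

  double dist(const Face& f, int i) const {
    return f.nx * X[i] + f.ny * Y[i] + f.nz * Z[i] - f.off;
  }

  void add_face(int a, int b, int c) {
    Face f; f.a = a; f.b = b; f.c = c; f.alive = true;
    plane(f);
    // orient outward: interior point must lie on the non-positive side
    if (f.nx * cx + f.ny * cy + f.nz * cz - f.off > 0) {
      std::swap(f.b, f.c);
      plane(f);
    }
    faces.push_back(f);
  }

  // returns false when the cloud is degenerate (caller handles)
  bool build() {
    const int n = (int)X.size();
    if (n < 4) return false;

    double xr = 0, yr = 0, zr = 0;
    {
      double x0 = X[0], x1 = X[0], y0 = Y[0], y1 = Y[0], z0 = Z[0], z1 = Z[0];
      for (int i = 1; i < n; ++i) {
        x0 = std::min(x0, X[i]); x1 = std::max(x1, X[i]);
        y0 = std::min(y0, Y[i]); y1 = std::max(y1, Y[i]);
        z0 = std::min(z0, Z[i]); z1 = std::max(z1, Z[i]);
      }
      xr = x1 - x0; yr = y1 - y0; zr = z1 - z0;
    }
    double scale = std::max(1.0, std::max(xr, std::max(yr, zr)));
    eps = 1e-9 * scale;

    // seed tetrahedron: extreme point pair, then max distance from line/plane
    int i0 = 0;
    for (int i = 1; i < n; ++i)
      if (X[i] < X[i0] || (X[i] == X[i0] && (Y[i] < Y[i0] ||
          (Y[i] == Y[i0] && Z[i] < Z[i0])))) i0 = i;
    int i1 = -1; double best = -1;
    for (int i = 0; i < n; ++i) {
      double dx = X[i] - X[i0], dy = Y[i] - Y[i0], dz = Z[i] - Z[i0];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) { best = d2; i1 = i; }
    }
    if (best <= eps * eps) return false;
    int i2 = -1; best = -1;
    {
      double ux = X[i1] - X[i0], uy = Y[i1] - Y[i0], uz = Z[i1] - Z[i0];
      double ul = std::sqrt(ux * ux + uy * uy + uz * uz);
      for (int i = 0; i < n; ++i) {
        double vx = X[i] - X[i0], vy = Y[i] - Y[i0], vz = Z[i] - Z[i0];
        double cxp = uy * vz - uz * vy, cyp = uz * vx - ux * vz, czp = ux * vy - uy * vx;
        double d = std::sqrt(cxp * cxp + cyp * cyp + czp * czp) / ul;
        if (d > best) { best = d; i2 = i; }
      }
    }
    if (best <= eps) return false;
    Face f0; f0.a = i0; f0.b = i1; f0.c = i2; plane(f0);
    int i3 = -1; best = -1;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(dist(f0, i));
      if (d > best) { best = d; i3 = i; }
    }
    if (best <= eps) return false; // all points coplanar

    cx = (X[i0] + X[i1] + X[i2] + X[i3]) / 4.0;
    cy = (Y[i0] + Y[i1] + Y[i2] + Y[i3]) / 4.0;
    cz = (Z[i0] + Z[i1] + Z[i2] + Z[i3]) / 4.0;
    add_face(i0, i1, i2);
    add_face(i0, i1, i3);
    add_face(i0, i2, i3);
    add_face(i1, i2, i3);

    std::vector<int> vis;
    std::unordered_set<long long> edges;
    for (int p = 0; p < n; ++p) {
      if (p == i0 || p == i1 || p == i2 || p == i3) continue;
      vis.clear();
      for (int fi = 0; fi < (int)faces.size(); ++fi)
        if (faces[fi].alive && dist(faces[fi], p) > eps) vis.push_back(fi);
      if (vis.empty()) continue;

      edges.clear();
      const long long N = (long long)n;
      for (int fi : vis) {
        const Face& f = faces[fi];
        edges.insert((long long)f.a * N + f.b);
        edges.insert((long long)f.b * N + f.c);
        edges.insert((long long)f.c * N + f.a);
      }
      // horizon = directed edges of visible faces whose reverse is not visible
      std::vector<std::pair<int, int>> horizon;
      for (int fi : vis) {
        const Face& f = faces[fi];
        int ea[3] = { f.a, f.b, f.c };
        for (int k = 0; k < 3; ++k) {
          int u = ea[k], v = ea[(k + 1) % 3];
          if (edges.find((long long)v * N + u) == edges.end())
            horizon.push_back(std::make_pair(u, v));
        }
      }
      for (int fi : vis) faces[fi].alive = false;
      for (size_t k = 0; k < horizon.size(); ++k)
        add_face(horizon[k].first, horizon[k].second, p);
    }
    return true;
  }
};

} // namespace

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_upper_envelope(NumericVector px, NumericVector py, NumericVector pz,
                                 IntegerVector qx, IntegerVector qy) {
  const int n = px.size();
  const int nq = qx.size();
  std::vector<double> X(px.begin(), px.end());
  std::vector<double> Y(py.begin(), py.end());
  std::vector<double> Z(pz.begin(), pz.end());

  HullBuilder hb(X, Y, Z);
  if (!hb.build())
    stop("degenerate point cloud reached the 3D hull kernel");

  // upper facets: outward normal with positive brightness component
  std::vector<int> upper;
  for (int fi = 0; fi < (int)hb.faces.size(); ++fi)
    if (hb.faces[fi].alive && hb.faces[fi].nz > 1e-9) upper.push_back(fi);
  if (upper.empty()) stop("hull has no upper facets");

  // deterministic facet order: sort by sorted vertex-index triple
  std::sort(upper.begin(), upper.end(), [&](int a, int b) {
    int va[3] = { hb.faces[a].a, hb.faces[a].b, hb.faces[a].c };
    int vb[3] = { hb.faces[b].a, hb.faces[b].b, hb.faces[b].c };
    std::sort(va, va + 3); std::sort(vb, vb + 3);
    if (va[0] != vb[0]) return va[0] < vb[0];
    if (va[1] != vb[1]) return va[1] < vb[1];
    return va[2] < vb[2];
  });

  // query lookup grid over the integer (x, y) footprint
  int qx0 = qx[0], qx1 = qx[0], qy0 = qy[0], qy1 = qy[0];
  for (int i = 1; i < nq; ++i) {
    qx0 = std::min(qx0, qx[i]); qx1 = std::max(qx1, qx[i]);
    qy0 = std::min(qy0, qy[i]); qy1 = std::max(qy1, qy[i]);
  }
  const int W = qx1 - qx0 + 1, H = qy1 - qy0 + 1;
  std::vector<int> lut((size_t)W * H, -1);
  for (int i = 0; i < nq; ++i)
    lut[(size_t)(qx[i] - qx0) * H + (qy[i] - qy0)] = i;

  NumericVector out(nq, NA_REAL);
  int remaining = nq;

  for (size_t u = 0; u < upper.size() && remaining > 0; ++u) {
    const Face& f = hb.faces[upper[u]];
    double ax = X[f.a], ay = Y[f.a];
    double bx = X[f.b], by = Y[f.b];
    double cx2 = X[f.c], cy2 = Y[f.c];
    double area2 = (bx - ax) * (cy2 - ay) - (by - ay) * (cx2 - ax);
    if (std::fabs(area2) < 1e-12) continue;
    double sgn = area2 > 0 ? 1.0 : -1.0;
    double tol = -1e-9 * std::fabs(area2) - 1e-12;
    int lo_x = (int)std::ceil(std::min(ax, std::min(bx, cx2)) - 1e-9);
    int hi_x = (int)std::floor(std::max(ax, std::max(bx, cx2)) + 1e-9);
    int lo_y = (int)std::ceil(std::min(ay, std::min(by, cy2)) - 1e-9);
    int hi_y = (int)std::floor(std::max(ay, std::max(by, cy2)) + 1e-9);
    lo_x = std::max(lo_x, qx0); hi_x = std::min(hi_x, qx1);
    lo_y = std::max(lo_y, qy0); hi_y = std::min(hi_y, qy1);
    for (int x = lo_x; x <= hi_x; ++x) {
      for (int y = lo_y; y <= hi_y; ++y) {
        int qi = lut[(size_t)(x - qx0) * H + (y - qy0)];
        if (qi < 0 || !NumericVector::is_na(out[qi])) continue;
        double e0 = sgn * ((bx - ax) * (y - ay) - (by - ay) * (x - ax));
        double e1 = sgn * ((cx2 - bx) * (y - by) - (cy2 - by) * (x - bx));
        double e2 = sgn * ((ax - cx2) * (y - cy2) - (ay - cy2) * (x - cx2));
        if (e0 >= tol && e1 >= tol && e2 >= tol) {
          out[qi] = (f.off - f.nx * x - f.ny * y) / f.nz;
          --remaining;
        }
      }
    }
  }

  // numeric fall-back for pixels missed by rasterization: the concave envelope
  // equals the minimum over all upper facet planes
  if (remaining > 0) {
    for (int i = 0; i < nq; ++i) {
      if (!NumericVector::is_na(out[i])) continue;
      double best = R_PosInf;
      for (size_t u = 0; u < upper.size(); ++u) {
        const Face& f = hb.faces[upper[u]];
        double v = (f.off - f.nx * qx[i] - f.ny * qy[i]) / f.nz;
        if (v < best) best = v;
      }
      out[i] = best;
    }
  }
  return out;
}
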