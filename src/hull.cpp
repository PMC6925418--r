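#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental 3D convex hull (beneath-beyond) with two consumers:
//  - cpp_hull_volume: volume of the hull of a point cloud;
//  - cpp_hull_inside_count: number of query points inside (or on) the
//    hull, used to rasterize the convex volume for the solidity feature.
// Degenerate inputs (all points coplanar) yield volume 0 / count -1.

struct Face { int a, b, c; double nx, ny, nz, off; bool alive; };

static inline void cross3(double ax, double ay, double az,
                          double bx, double by, double bz,
                          double &cx, double &cy, double &cz) {
  cx = ay * bz - az * by;
  cy = az * bx - ax * bz;
  cz = ax * by - ay * bx;
}

// builds the hull; returns false when degenerate
static bool build_hull(const std::vector<double> &X,
                       const std::vector<double> &Y,
                       const std::vector<double> &Z,
                       double eps, std::vector<Face> &faces,
                       double &ox, double &oy, double &oz) {
  int n = (int)X.size();
  if (n < 4) return false;
  int p0 = 0, p1 = -1;
  for (int i = 1; i < n; i++)
    if (X[i] < X[p0] || (X[i] == X[p0] && (Y[i] < Y[p0] ||
        (Y[i] == Y[p0] && Z[i] < Z[p0])))) p0 = i;
  double best = -1.0;
  for (int i = 0; i < n; i++) {
    double dx = X[i] - X[p0], dy = Y[i] - Y[p0], dz = Z[i] - Z[p0];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > best) { best = d2; p1 = i; }
  }
  if (best <= eps * eps) return false;
  double span = std::sqrt(best);
  int p2 = -1; best = -1.0;
  for (int i = 0; i < n; i++) {
    double cx, cy, cz;
    cross3(X[p1] - X[p0], Y[p1] - Y[p0], Z[p1] - Z[p0],
           X[i] - X[p0], Y[i] - Y[p0], Z[i] - Z[p0], cx, cy, cz);
    double a2 = cx * cx + cy * cy + cz * cz;
    if (a2 > best) { best = a2; p2 = i; }
  }
  if (std::sqrt(best) <= eps * span) return false;  // collinear
  double nx0, ny0, nz0;
  cross3(X[p1] - X[p0], Y[p1] - Y[p0], Z[p1] - Z[p0],
         X[p2] - X[p0], Y[p2] - Y[p0], Z[p2] - Z[p0], nx0, ny0, nz0);
  int p3 = -1; best = 0.0;
  for (int i = 0; i < n; i++) {
    double v = nx0 * (X[i] - X[p0]) + ny0 * (Y[i] - Y[p0]) +
               nz0 * (Z[i] - Z[p0]);
    if (std::fabs(v) > std::fabs(best)) { best = v; p3 = i; }
  }
  double nrm = std::sqrt(nx0 * nx0 + ny0 * ny0 + nz0 * nz0);
  if (std::fabs(best) / nrm <= eps) return false;  // coplanar

  ox = (X[p0] + X[p1] + X[p2] + X[p3]) / 4.0;
  oy = (Y[p0] + Y[p1] + Y[p2] + Y[p3]) / 4.0;
  oz = (Z[p0] + Z[p1] + Z[p2] + Z[p3]) / 4.0;

  faces.clear();
  int init[4][3] = {{p0, p1, p2}, {p0, p1, p3}, {p0, p2, p3}, {p1, p2, p3}};
  for (int f = 0; f < 4; f++) {
    Face fc; fc.a = init[f][0]; fc.b = init[f][1]; fc.c = init[f][2];
    double cx, cy, cz;
    cross3(X[fc.b] - X[fc.a], Y[fc.b] - Y[fc.a], Z[fc.b] - Z[fc.a],
           X[fc.c] - X[fc.a], Y[fc.c] - Y[fc.a], Z[fc.c] - Z[fc.a],
           cx, cy, cz);
    double off = cx * X[fc.a] + cy * Y[fc.a] + cz * Z[fc.a];
    if (cx * ox + cy * oy + cz * oz > off) {
      int t = fc.b; fc.b = fc.c; fc.c = t;
      cx = -cx; cy = -cy; cz = -cz; off = -off;
    }
    fc.nx = cx; fc.ny = cy; fc.nz = cz; fc.off = off; fc.alive = true;
    faces.push_back(fc);
  }

  for (int i = 0; i < n; i++) {
    if (i == p0 || i == p1 || i == p2 || i == p3) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); f++) {
      if (!faces[f].alive) continue;
      double nf = std::sqrt(faces[f].nx * faces[f].nx +
                            faces[f].ny * faces[f].ny +
                            faces[f].nz * faces[f].nz);
      double d = (faces[f].nx * X[i] + faces[f].ny * Y[i] +
                  faces[f].nz * Z[i] - faces[f].off) / nf;
      if (d > eps) visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    // horizon = directed edges of visible faces whose reverse edge does
    // not belong to a visible face
    std::map<std::pair<int, int>, int> edges;
    for (size_t v = 0; v < visible.size(); v++) {
      Face &fc = faces[visible[v]];
      int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
      for (int k = 0; k < 3; k++)
        edges[std::make_pair(e[k][0], e[k][1])] += 1;
      fc.alive = false;
    }
    for (std::map<std::pair<int, int>, int>::iterator it = edges.begin();
         it != edges.end(); ++it) {
      int u = it->first.first, v = it->first.second;
      if (edges.count(std::make_pair(v, u))) continue;
      Face fc; fc.a = u; fc.b = v; fc.c = i;
      double cx, cy, cz;
      cross3(X[v] - X[u], Y[v] - Y[u], Z[v] - Z[u],
             X[i] - X[u], Y[i] - Y[u], Z[i] - Z[u], cx, cy, cz);
      double off = cx * X[u] + cy * Y[u] + cz * Z[u];
      if (cx * ox + cy * oy + cz * oz > off) {
        int t = fc.b; fc.b = fc.c; fc.c = t;
        cx = -cx; cy = -cy; cz = -cz; off = -off;
      }
      fc.nx = cx; fc.ny = cy; fc.nz = cz; fc.off = off; fc.alive = true;
      faces.push_back(fc);
    }
  }
  return true;
}

static double points_scale(const NumericMatrix &pts) {
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < pts.nrow(); i++)
    for (int d = 0; d < 3; d++) {
      double v = pts(i, d);
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  double scale = 0.0;
  for (int d = 0; d < 3; d++) scale = std::max(scale, hi[d] - lo[d]);
  return scale;
}

// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; i++) {
    X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2);
  }
  double scale = points_scale(pts);
  if (scale <= 0) return 0.0;
  std::vector<Face> faces;
  double ox, oy, oz;
  if (!build_hull(X, Y, Z, 1e-9 * scale, faces, ox, oy, oz)) return 0.0;
  double vol = 0.0;
  for (size_t f = 0; f < faces.size(); f++) {
    if (!faces[f].alive) continue;
    const Face &fc = faces[f];
    double ax = X[fc.a] - ox, ay = Y[fc.a] - oy, az = Z[fc.a] - oz;
    double bx = X[fc.b] - ox, by = Y[fc.b] - oy, bz = Z[fc.b] - oz;
    double cx = X[fc.c] - ox, cy = Y[fc.c] - oy, cz = Z[fc.c] - oz;
    double kx, ky, kz;
    cross3(bx, by, bz, cx, cy, cz, kx, ky, kz);
    vol += (ax * kx + ay * ky + az * kz) / 6.0;
  }
  return vol;
}

// [[Rcpp::export]]
int cpp_hull_inside_count(NumericMatrix pts, NumericMatrix queries) {
  int n = pts.nrow();
  if (n < 4) return -1;
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; i++) {
    X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2);
  }
  double scale = points_scale(pts);
  if (scale <= 0) return -1;
  double eps = 1e-9 * scale;
  std::vector<Face> faces;
  double ox, oy, oz;
  if (!build_hull(X, Y, Z, eps, faces, ox, oy, oz)) return -1;
  std::vector<Face> alive;
  for (size_t f = 0; f < faces.size(); f++)
    if (faces[f].alive) {
      Face fc = faces[f];
      double nf = std::sqrt(fc.nx * fc.nx + fc.ny * fc.ny + fc.nz * fc.nz);
      fc.nx /= nf; fc.ny /= nf; fc.nz /= nf; fc.off /= nf;
      alive.push_back(fc);
    }
  int count = 0;
  double tol = 1e-7 * scale;  // points on a face count as inside
  for (int q = 0; q < queries.nrow(); q++) {
    double qx = queries(q, 0), qy = queries(q, 1), qz = queries(q, 2);
    bool inside = true;
    for (size_t f = 0; f < alive.size(); f++) {
      if (alive[f].nx * qx + alive[f].ny * qy + alive[f].nz * qz -
          alive[f].off > tol) { inside = false; break; }
    }
    if (inside) count++;
  }
  return count;
}
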