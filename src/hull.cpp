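#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <map>
using namespace Rcpp;

// Incremental 3D convex hull. Returns 1-based triangle indices into the input
// point matrix, oriented so that triangle normals point away from the hull
// interior. Interior points simply never appear in any triangle.

namespace {

struct Face {
  int a, b, c;     // vertex indices (0-based)
  double nx, ny, nz, off; // outward plane: n . x = off
  bool alive;
};

inline void plane(const std::vector<std::array<double,3>>& P, Face& f,
                  const std::array<double,3>& inside) {
  const auto &A = P[f.a], &B = P[f.b], &C = P[f.c];
  double ux = B[0]-A[0], uy = B[1]-A[1], uz = B[2]-A[2];
  double vx = C[0]-A[0], vy = C[1]-A[1], vz = C[2]-A[2];
  f.nx = uy*vz - uz*vy;
  f.ny = uz*vx - ux*vz;
  f.nz = ux*vy - uy*vx;
  f.off = f.nx*A[0] + f.ny*A[1] + f.nz*A[2];
  // orient away from the interior reference point
  double s = f.nx*inside[0] + f.ny*inside[1] + f.nz*inside[2] - f.off;
  if (s > 0) { std::swap(f.b, f.c); f.nx = -f.nx; f.ny = -f.ny; f.nz = -f.nz; f.off = -f.off; }
}

inline double dist(const Face& f, const std::array<double,3>& p) {
  return f.nx*p[0] + f.ny*p[1] + f.nz*p[2] - f.off;
}

} // namespace

// [[Rcpp::export(name = ".hull3d")]]
IntegerMatrix hull3d(NumericMatrix pts, double joggle = 0.0) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3D hull");
  std::vector<std::array<double,3>> P(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P[i] = { pts(i,0), pts(i,1), pts(i,2) };
    for (int d = 0; d < 3; ++d) scale = std::max(scale, std::fabs(P[i][d]));
  }
  if (scale == 0.0) scale = 1.0;
  if (joggle > 0.0) {
    // deterministic symbolic perturbation to break cospherical degeneracies
    uint32_t s = 2463534242u;
    for (int i = 0; i < n; ++i) {
      for (int d = 0; d < 3; ++d) {
        s ^= s << 13; s ^= s >> 17; s ^= s << 5; // xorshift32
        double u = (double)s / 4294967296.0 - 0.5;
        P[i][d] += 2.0 * u * joggle * scale;
      }
    }
  }
  const double eps = 1e-10 * scale;

  // initial simplex: extreme point, farthest point, max-area third, max-height fourth
  int i0 = 0, i1 = -1;
  for (int i = 1; i < n; ++i) if (P[i] < P[i0]) i0 = i;
  {
    double best = -1.0;
    for (int i = 0; i < n; ++i) {
      if (i == i0) continue;
      double d2 = 0; for (int d = 0; d < 3; ++d) { double t = P[i][d]-P[i0][d]; d2 += t*t; }
      if (d2 > best) { best = d2; i1 = i; }
    }
    if (i1 < 0 || best <= eps*eps) stop("degenerate input: all points coincide");
  }
  int i2 = -1;
  {
    double best = -1.0;
    for (int i = 0; i < n; ++i) {
      if (i == i0 || i == i1) continue;
      double ux = P[i1][0]-P[i0][0], uy = P[i1][1]-P[i0][1], uz = P[i1][2]-P[i0][2];
      double vx = P[i][0]-P[i0][0],  vy = P[i][1]-P[i0][1],  vz = P[i][2]-P[i0][2];
      double cx = uy*vz-uz*vy, cy = uz*vx-ux*vz, cz = ux*vy-uy*vx;
      double a2 = cx*cx + cy*cy + cz*cz;
      if (a2 > best) { best = a2; i2 = i; }
    }
    if (i2 < 0 || best <= eps*eps*scale*scale) stop("degenerate input: points are collinear");
  }
  int i3 = -1;
  {
    double ux = P[i1][0]-P[i0][0], uy = P[i1][1]-P[i0][1], uz = P[i1][2]-P[i0][2];
    double vx = P[i2][0]-P[i0][0], vy = P[i2][1]-P[i0][1], vz = P[i2][2]-P[i0][2];
    double cx = uy*vz-uz*vy, cy = uz*vx-ux*vz, cz = ux*vy-uy*vx;
    double nrm = std::sqrt(cx*cx + cy*cy + cz*cz);
    cx /= nrm; cy /= nrm; cz /= nrm;
    double best = -1.0;
    for (int i = 0; i < n; ++i) {
      if (i == i0 || i == i1 || i == i2) continue;
      double h = std::fabs(cx*(P[i][0]-P[i0][0]) + cy*(P[i][1]-P[i0][1]) + cz*(P[i][2]-P[i0][2]));
      if (h > best) { best = h; i3 = i; }
    }
    if (i3 < 0 || best <= 10*eps) stop("degenerate input: points are coplanar");
  }

  std::array<double,3> inside = {
    (P[i0][0]+P[i1][0]+P[i2][0]+P[i3][0]) / 4.0,
    (P[i0][1]+P[i1][1]+P[i2][1]+P[i3][1]) / 4.0,
    (P[i0][2]+P[i1][2]+P[i2][2]+P[i3][2]) / 4.0
  };

  std::vector<Face> faces;
  faces.reserve(8*n);
  auto add_face = [&](int a, int b, int c) {
    Face f; f.a = a; f.b = b; f.c = c; f.alive = true;
    plane(P, f, inside);
    faces.push_back(f);
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  std::vector<char> used(n, 0);
  used[i0] = used[i1] = used[i2] = used[i3] = 1;

  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    // visible faces
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && dist(faces[f], P[p]) > eps) vis.push_back((int)f);
    if (vis.empty()) continue; // interior point
    // horizon: edges appearing exactly once among visible faces
    std::map<std::pair<int,int>, std::pair<int,int>> edge_count; // sorted edge -> (count, oriented-first)
    for (int fi : vis) {
      const Face& f = faces[fi];
      const int e[3][2] = { {f.a,f.b}, {f.b,f.c}, {f.c,f.a} };
      for (int k = 0; k < 3; ++k) {
        int u = e[k][0], v = e[k][1];
        auto key = std::make_pair(std::min(u,v), std::max(u,v));
        auto it = edge_count.find(key);
        if (it == edge_count.end()) edge_count[key] = { 1, u == key.first ? 1 : -1 };
        else it->second.first += 1;
      }
    }
    for (int fi : vis) faces[fi].alive = false;
    for (auto& kv : edge_count) {
      if (kv.second.first != 1) continue;
      add_face(kv.first.first, kv.first.second, p);
    }
    used[p] = 1;
  }

  int nf = 0;
  for (auto& f : faces) if (f.alive) ++nf;
  IntegerMatrix out(nf, 3);
  int r = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    out(r,0) = f.a + 1; out(r,1) = f.b + 1; out(r,2) = f.c + 1;
    ++r;
  }
  return out;
}
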