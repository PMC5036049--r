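// Incremental 3D Delaunay tetrahedralization (Bowyer-Watson) with a
// symbolic vertex at infinity covering the convex hull, so every face is
// shared by exactly two cells and cavity boundaries are unambiguous.
// Inputs are expected in general position (callers joggle coordinates).
#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>

using namespace Rcpp;

namespace {

const int INF = -1; // symbolic infinite vertex

struct Cell {
  int v[4];       // vertex indices, INF allowed in at most one slot
  bool alive;
  // cached circumsphere (finite cells only)
  double cx, cy, cz, r2;
  // cached outward plane for infinite cells: sign s of orient3d(a,b,c,q)
  // for q strictly inside the hull; conflict iff sign(orient3d(a,b,c,p)) == -s
  int fa, fb, fc; // the finite facet of an infinite cell
  double inward_sign;
};

inline double orient3d(const double* p, int a, int b, int c, int d) {
  double adx = p[3*a] - p[3*d], ady = p[3*a+1] - p[3*d+1], adz = p[3*a+2] - p[3*d+2];
  double bdx = p[3*b] - p[3*d], bdy = p[3*b+1] - p[3*d+1], bdz = p[3*b+2] - p[3*d+2];
  double cdx = p[3*c] - p[3*d], cdy = p[3*c+1] - p[3*d+1], cdz = p[3*c+2] - p[3*d+2];
  return adx * (bdy * cdz - bdz * cdy)
       - ady * (bdx * cdz - bdz * cdx)
       + adz * (bdx * cdy - bdy * cdx);
}

// circumcenter of tetrahedron (a,b,c,d); returns false if degenerate
inline bool circumsphere(const double* p, int a, int b, int c, int d,
                         double& cx, double& cy, double& cz, double& r2) {
  double ax = p[3*a], ay = p[3*a+1], az = p[3*a+2];
  double M[3][3], rhs[3];
  int idx[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    double dx = p[3*idx[i]] - ax, dy = p[3*idx[i]+1] - ay, dz = p[3*idx[i]+2] - az;
    M[i][0] = dx; M[i][1] = dy; M[i][2] = dz;
    rhs[i] = 0.5 * (dx*dx + dy*dy + dz*dz);
  }
  double det = M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
             - M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
             + M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
  if (std::fabs(det) < 1e-30) return false;
  double inv = 1.0 / det;
  double ux = inv * ( rhs[0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
                    - M[0][1]*(rhs[1]*M[2][2]-M[1][2]*rhs[2])
                    + M[0][2]*(rhs[1]*M[2][1]-M[1][1]*rhs[2]) );
  double uy = inv * ( M[0][0]*(rhs[1]*M[2][2]-M[1][2]*rhs[2])
                    - rhs[0]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
                    + M[0][2]*(M[1][0]*rhs[2]-rhs[1]*M[2][0]) );
  double uz = inv * ( M[0][0]*(M[1][1]*rhs[2]-rhs[1]*M[2][1])
                    - M[0][1]*(M[1][0]*rhs[2]-rhs[1]*M[2][0])
                    + rhs[0]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]) );
  cx = ax + ux; cy = ay + uy; cz = az + uz;
  r2 = ux*ux + uy*uy + uz*uz;
  return true;
}

struct Face {
  int a, b, c; // sorted, INF may appear as -1 in slot a
  bool operator<(const Face& o) const {
    if (a != o.a) return a < o.a;
    if (b != o.b) return b < o.b;
    return c < o.c;
  }
};

inline Face make_face(int x, int y, int z) {
  int v[3] = {x, y, z};
  if (v[0] > v[1]) std::swap(v[0], v[1]);
  if (v[1] > v[2]) std::swap(v[1], v[2]);
  if (v[0] > v[1]) std::swap(v[0], v[1]);
  Face f; f.a = v[0]; f.b = v[1]; f.c = v[2];
  return f;
}

} // namespace

// Returns an m x 4 integer matrix of 0-based vertex indices of the finite
// Delaunay tetrahedra. `pts` is n x 3, n >= 4, general position assumed.
// [[Rcpp::export(name = ".delaunay3d")]]
IntegerMatrix delaunay3d(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3D tessellation");
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i) {
    p[3*i] = pts(i, 0); p[3*i+1] = pts(i, 1); p[3*i+2] = pts(i, 2);
  }

  // pick 4 affinely independent seed points (greedy, deterministic)
  std::vector<int> seed;
  seed.push_back(0);
  for (int i = 1; i < n && (int)seed.size() < 2; ++i) {
    double dx = p[3*i]-p[0], dy = p[3*i+1]-p[1], dz = p[3*i+2]-p[2];
    if (dx*dx + dy*dy + dz*dz > 1e-20) seed.push_back(i);
  }
  for (int i = 1; i < n && (int)seed.size() < 3; ++i) {
    if (i == seed[1]) continue;
    double ux = p[3*seed[1]]-p[3*seed[0]], uy = p[3*seed[1]+1]-p[3*seed[0]+1], uz = p[3*seed[1]+2]-p[3*seed[0]+2];
    double vx = p[3*i]-p[3*seed[0]], vy = p[3*i+1]-p[3*seed[0]+1], vz = p[3*i+2]-p[3*seed[0]+2];
    double cxp = uy*vz-uz*vy, cyp = uz*vx-ux*vz, czp = ux*vy-uy*vx;
    if (cxp*cxp + cyp*cyp + czp*czp > 1e-20) seed.push_back(i);
  }
  for (int i = 1; i < n && (int)seed.size() < 4; ++i) {
    if (i == seed[1] || i == seed[2]) continue;
    if (std::fabs(orient3d(p.data(), seed[0], seed[1], seed[2], i)) > 1e-18)
      seed.push_back(i);
  }
  if ((int)seed.size() < 4)
    stop("degenerate point set: no affinely independent tetrahedron found");

  std::vector<Cell> cells;
  cells.reserve(16 * n);

  // running interior reference point = centroid of inserted points
  double gx = 0, gy = 0, gz = 0;
  int ninserted = 0;

  auto add_finite = [&](int a, int b, int c, int d) {
    Cell t; t.v[0]=a; t.v[1]=b; t.v[2]=c; t.v[3]=d; t.alive = true;
    if (!circumsphere(p.data(), a, b, c, d, t.cx, t.cy, t.cz, t.r2))
      stop("degenerate tetrahedron encountered; increase joggle");
    t.fa = t.fb = t.fc = -2; t.inward_sign = 0;
    cells.push_back(t);
  };
  auto add_infinite = [&](int a, int b, int c) {
    Cell t; t.v[0]=a; t.v[1]=b; t.v[2]=c; t.v[3]=INF; t.alive = true;
    t.fa=a; t.fb=b; t.fc=c;
    // centroid of current points is strictly inside the hull
    double qx = gx / ninserted, qy = gy / ninserted, qz = gz / ninserted;
    double adx = p[3*a]-qx, ady = p[3*a+1]-qy, adz = p[3*a+2]-qz;
    double bdx = p[3*b]-qx, bdy = p[3*b+1]-qy, bdz = p[3*b+2]-qz;
    double cdx = p[3*c]-qx, cdy = p[3*c+1]-qy, cdz = p[3*c+2]-qz;
    double o = adx*(bdy*cdz-bdz*cdy) - ady*(bdx*cdz-bdz*cdx) + adz*(bdx*cdy-bdy*cdx);
    t.inward_sign = (o > 0) ? 1.0 : -1.0;
    t.cx=t.cy=t.cz=t.r2=0;
    cells.push_back(t);
  };

  // initial tetrahedron + 4 infinite cells
  for (int k = 0; k < 4; ++k) {
    gx += p[3*seed[k]]; gy += p[3*seed[k]+1]; gz += p[3*seed[k]+2];
    ++ninserted;
  }
  add_finite(seed[0], seed[1], seed[2], seed[3]);
  add_infinite(seed[0], seed[1], seed[2]);
  add_infinite(seed[0], seed[1], seed[3]);
  add_infinite(seed[0], seed[2], seed[3]);
  add_infinite(seed[1], seed[2], seed[3]);

  std::vector<bool> used(n, false);
  for (int k = 0; k < 4; ++k) used[seed[k]] = true;

  std::vector<int> conflict;
  std::map<Face, std::pair<int,int>> faces; // face -> (count, opposite vertex)

  for (int ip = 0; ip < n; ++ip) {
    if (used[ip]) continue;
    const double px = p[3*ip], py = p[3*ip+1], pz = p[3*ip+2];

    conflict.clear();
    for (size_t ci = 0; ci < cells.size(); ++ci) {
      Cell& t = cells[ci];
      if (!t.alive) continue;
      bool bad;
      if (t.v[3] == INF) {
        double o = orient3d(p.data(), t.fa, t.fb, t.fc, ip);
        bad = (o * t.inward_sign < 0); // p strictly outside this hull facet
      } else {
        double dx = px - t.cx, dy = py - t.cy, dz = pz - t.cz;
        bad = (dx*dx + dy*dy + dz*dz < t.r2);
      }
      if (bad) conflict.push_back((int)ci);
    }
    if (conflict.empty())
      stop("point located in no conflict region (degenerate input)");

    faces.clear();
    for (int ci : conflict) {
      const Cell& t = cells[ci];
      for (int f = 0; f < 4; ++f) {
        Face fc = make_face(t.v[(f+1)%4], t.v[(f+2)%4], t.v[(f+3)%4]);
        auto it = faces.find(fc);
        if (it == faces.end()) faces[fc] = std::make_pair(1, t.v[f]);
        else it->second.first += 1;
      }
      cells[ci].alive = false;
    }

    gx += px; gy += py; gz += pz; ++ninserted; used[ip] = true;

    for (auto& kv : faces) {
      if (kv.second.first != 1) continue; // interior face of the cavity
      const Face& f = kv.first;
      if (f.a == INF) add_infinite(f.b, f.c, ip); // new hull facet with p
      else add_finite(f.a, f.b, f.c, ip);
    }
  }

  int m = 0;
  for (const Cell& t : cells) if (t.alive && t.v[3] != INF) ++m;
  IntegerMatrix out(m, 4);
  int r = 0;
  for (const Cell& t : cells) {
    if (!t.alive || t.v[3] == INF) continue;
    for (int k = 0; k < 4; ++k) out(r, k) = t.v[k];
    ++r;
  }
  return out;
}
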