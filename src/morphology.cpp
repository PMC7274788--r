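// Low-level 3D voxel and point-cloud primitives.
// Arrays are R arrays with dim = c(nz, ny, nx), column-major:
// linear index = z + nz * (y + ny * x), 0-based here.
#include <Rcpp.h>
#include <queue>
#include <stack>
#include <algorithm>
#include <cmath>
#include <map>
#include <array>
#include <unordered_map>
using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// 6- and 26-neighbourhood offsets
static void neighbour_offsets(int conn, std::vector<std::array<int,3>>& off) {
  off.clear();
  if (conn == 6) {
    off = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dz || dy || dx) off.push_back({{dz,dy,dx}});
  }
}

// [[Rcpp::export(name = ".cpp_median3")]]
NumericVector cpp_median3(NumericVector vol, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(vol.size());
  std::vector<double> buf; buf.reserve(27);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = z + dz; if (zz < 0 || zz >= nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = x + dx; if (xx < 0 || xx >= nx) continue;
              buf.push_back(vol[idx3(zz, yy, xx, nz, ny)]);
            }
          }
        }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
          med = 0.5 * (med + buf[m - 1]);
        }
        out[idx3(z, y, x, nz, ny)] = med;
      }
  out.attr("dim") = dim;
  return out;
}

// separable Gaussian, reflect boundary, truncated at 4 sigma
static void blur_axis(std::vector<double>& v, std::vector<double>& tmp,
                      int nz, int ny, int nx, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double& w : k) w /= s;
  int n[3] = {nz, ny, nx};
  int len = n[axis];
  auto reflect = [len](int i) {
    while (i < 0 || i >= len) { if (i < 0) i = -i - 1; if (i >= len) i = 2 * len - i - 1; }
    return i;
  };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int c[3] = {z, y, x};
        double acc = 0;
        for (int i = -r; i <= r; ++i) {
          int cc[3] = {c[0], c[1], c[2]};
          cc[axis] = reflect(c[axis] + i);
          acc += k[i + r] * v[idx3(cc[0], cc[1], cc[2], nz, ny)];
        }
        tmp[idx3(z, y, x, nz, ny)] = acc;
      }
  v.swap(tmp);
}

// [[Rcpp::export(name = ".cpp_gaussian3d")]]
NumericVector cpp_gaussian3d(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> v(vol.begin(), vol.end()), tmp(v.size());
  for (int ax = 0; ax < 3; ++ax) blur_axis(v, tmp, nz, ny, nx, ax, sigma[ax]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// connected-component labelling of a logical mask
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<std::array<int,3>> off;
  neighbour_offsets(connectivity, off);
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::stack<int> st;
  for (int i = 0; i < mask.size(); ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next; st.push(i);
    while (!st.empty()) {
      int j = st.top(); st.pop();
      int x = j / (nz * ny), rem = j % (nz * ny), y = rem / nz, z = rem % nz;
      for (auto& o : off) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int jj = idx3(zz, yy, xx, nz, ny);
        if (mask[jj] && !lab[jj]) { lab[jj] = next; st.push(jj); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// seeded watershed: priority flood on topography, 6-connected expansion.
// seeds: 0 = unlabelled; every voxel receives a label.
// [[Rcpp::export(name = ".cpp_watershed3d")]]
IntegerVector cpp_watershed3d(NumericVector topo, IntegerVector seeds, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<std::array<int,3>> off;
  neighbour_offsets(6, off);
  IntegerVector lab = clone(seeds);
  struct Node { double h; long long order; int idx; };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.h != b.h) return a.h > b.h;
      return a.order > b.order; // FIFO among equal heights
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long long counter = 0;
  std::vector<char> queued(topo.size(), 0);
  for (int i = 0; i < seeds.size(); ++i)
    if (seeds[i] > 0) { pq.push({topo[i], counter++, i}); queued[i] = 1; }
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int j = nd.idx;
    int x = j / (nz * ny), rem = j % (nz * ny), y = rem / nz, z = rem % nz;
    for (auto& o : off) {
      int zz = z + o[0], yy = y + o[1], xx = x + o[2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int jj = idx3(zz, yy, xx, nz, ny);
      if (lab[jj] == 0 && !queued[jj]) {
        lab[jj] = lab[j];
        pq.push({topo[jj], counter++, jj});
        queued[jj] = 1;
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// exact median of all pairwise distances (n small enough to enumerate)
// [[Rcpp::export(name = ".cpp_median_pairwise")]]
double cpp_median_pairwise(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<double> d;
  d.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dz = pts(i,0) - pts(j,0), dy = pts(i,1) - pts(j,1), dx = pts(i,2) - pts(j,2);
      d.push_back(std::sqrt(dz*dz + dy*dy + dx*dx));
    }
  size_t m = d.size() / 2;
  std::nth_element(d.begin(), d.begin() + m, d.end());
  double med = d[m];
  if (d.size() % 2 == 0) {
    std::nth_element(d.begin(), d.begin() + m - 1, d.begin() + m);
    med = 0.5 * (med + d[m - 1]);
  }
  return med;
}

// number of points within radius (inclusive) of each point, self included,
// via uniform grid hashing
// [[Rcpp::export(name = ".cpp_count_within_radius")]]
IntegerVector cpp_count_within_radius(NumericMatrix pts, double radius) {
  int n = pts.nrow();
  IntegerVector out(n);
  if (radius <= 0) {
    // degenerate radius: only exactly coincident points count
    std::map<std::array<double,3>, int> tally;
    for (int i = 0; i < n; ++i)
      tally[{{pts(i,0), pts(i,1), pts(i,2)}}]++;
    for (int i = 0; i < n; ++i)
      out[i] = tally[{{pts(i,0), pts(i,1), pts(i,2)}}];
    return out;
  }
  double cell = radius;
  auto key = [cell](double z, double y, double x) {
    long long kz = (long long)std::floor(z / cell);
    long long ky = (long long)std::floor(y / cell);
    long long kx = (long long)std::floor(x / cell);
    return (kz * 73856093LL) ^ (ky * 19349663LL) ^ (kx * 83492791LL);
  };
  std::unordered_map<long long, std::vector<int>> grid;
  grid.reserve(n * 2);
  for (int i = 0; i < n; ++i)
    grid[key(pts(i,0), pts(i,1), pts(i,2))].push_back(i);
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    long long bz = (long long)std::floor(pts(i,0) / cell);
    long long by = (long long)std::floor(pts(i,1) / cell);
    long long bx = (long long)std::floor(pts(i,2) / cell);
    for (long long dz = -1; dz <= 1; ++dz)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dx = -1; dx <= 1; ++dx) {
          long long k = ((bz+dz) * 73856093LL) ^ ((by+dy) * 19349663LL) ^ ((bx+dx) * 83492791LL);
          auto it = grid.find(k);
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double ddz = pts(i,0)-pts(j,0), ddy = pts(i,1)-pts(j,1), ddx = pts(i,2)-pts(j,2);
            if (ddz*ddz + ddy*ddy + ddx*ddx <= r2) ++cnt;
          }
        }
    out[i] = cnt;
  }
  return out;
}

// count ref-points within radius (inclusive) of each query point, via a
// uniform grid built on ref
// [[Rcpp::export(name = ".cpp_count_within_radius_ref")]]
IntegerVector cpp_count_within_radius_ref(NumericMatrix pts, NumericMatrix ref,
                                          double radius) {
  int n = pts.nrow(), m = ref.nrow();
  IntegerVector out(n);
  double cell = radius;
  auto key = [cell](double z, double y, double x) {
    long long kz = (long long)std::floor(z / cell);
    long long ky = (long long)std::floor(y / cell);
    long long kx = (long long)std::floor(x / cell);
    return (kz * 73856093LL) ^ (ky * 19349663LL) ^ (kx * 83492791LL);
  };
  std::unordered_map<long long, std::vector<int>> grid;
  grid.reserve(m * 2);
  for (int i = 0; i < m; ++i)
    grid[key(ref(i,0), ref(i,1), ref(i,2))].push_back(i);
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    long long bz = (long long)std::floor(pts(i,0) / cell);
    long long by = (long long)std::floor(pts(i,1) / cell);
    long long bx = (long long)std::floor(pts(i,2) / cell);
    for (long long dz = -1; dz <= 1; ++dz)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dx = -1; dx <= 1; ++dx) {
          long long k = ((bz+dz) * 73856093LL) ^ ((by+dy) * 19349663LL) ^ ((bx+dx) * 83492791LL);
          auto it = grid.find(k);
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double ddz = pts(i,0)-ref(j,0), ddy = pts(i,1)-ref(j,1), ddx = pts(i,2)-ref(j,2);
            if (ddz*ddz + ddy*ddy + ddx*ddx <= r2) ++cnt;
          }
        }
    out[i] = cnt;
  }
  return out;
}

// per-point percentiles of distances to all other points
// (linear interpolation between order statistics, R quantile type 7)
// [[Rcpp::export(name = ".cpp_pd_percentiles")]]
NumericMatrix cpp_pd_percentiles(NumericMatrix pts, NumericVector probs) {
  int n = pts.nrow(), np = probs.size();
  NumericMatrix out(n, np);
  std::vector<double> d(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dz = pts(i,0)-pts(j,0), dy = pts(i,1)-pts(j,1), dx = pts(i,2)-pts(j,2);
      d[m++] = std::sqrt(dz*dz + dy*dy + dx*dx);
    }
    for (int p = 0; p < np; ++p) {
      double h = (m - 1) * probs[p];
      int lo = (int)std::floor(h);
      std::nth_element(d.begin(), d.begin() + lo, d.begin() + m);
      double vlo = d[lo], vhi = vlo;
      if (lo + 1 < m)
        vhi = *std::min_element(d.begin() + lo + 1, d.begin() + m);
      out(i, p) = vlo + (h - lo) * (vhi - vlo);
    }
  }
  return out;
}

// ---- incremental 3D convex hull (surface area only) ----
struct Face { int a, b, c; double nx, ny, nz, d; bool alive; };

static void face_plane(const NumericMatrix& P, Face& f) {
  double ux = P(f.b,0)-P(f.a,0), uy = P(f.b,1)-P(f.a,1), uz = P(f.b,2)-P(f.a,2);
  double vx = P(f.c,0)-P(f.a,0), vy = P(f.c,1)-P(f.a,1), vz = P(f.c,2)-P(f.a,2);
  f.nx = uy*vz - uz*vy; f.ny = uz*vx - ux*vz; f.nz = ux*vy - uy*vx;
  f.d = f.nx*P(f.a,0) + f.ny*P(f.a,1) + f.nz*P(f.a,2);
}

// [[Rcpp::export(name = ".cpp_convhull_area")]]
double cpp_convhull_area(NumericMatrix P) {
  int n = P.nrow();
  if (n < 4) return NA_REAL;
  // scale for tolerance
  double scale = 0;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) scale = std::max(scale, std::fabs(P(i,k)));
  double eps = 1e-9 * std::max(scale, 1.0);
  // initial non-degenerate tetrahedron
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n && i1 < 0; ++i) {
    double d = std::fabs(P(i,0)-P(i0,0)) + std::fabs(P(i,1)-P(i0,1)) + std::fabs(P(i,2)-P(i0,2));
    if (d > eps) i1 = i;
  }
  if (i1 < 0) return NA_REAL;
  for (int i = 1; i < n && i2 < 0; ++i) {
    if (i == i1) continue;
    double ux = P(i1,0)-P(i0,0), uy = P(i1,1)-P(i0,1), uz = P(i1,2)-P(i0,2);
    double vx = P(i,0)-P(i0,0), vy = P(i,1)-P(i0,1), vz = P(i,2)-P(i0,2);
    double cx = uy*vz-uz*vy, cy = uz*vx-ux*vz, cz = ux*vy-uy*vx;
    if (cx*cx + cy*cy + cz*cz > eps*eps) i2 = i;
  }
  if (i2 < 0) return NA_REAL;
  Face base{i0, i1, i2, 0,0,0,0, true};
  face_plane(P, base);
  for (int i = 0; i < n && i3 < 0; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double s = base.nx*P(i,0) + base.ny*P(i,1) + base.nz*P(i,2) - base.d;
    if (std::fabs(s) > eps) i3 = i;
  }
  if (i3 < 0) return NA_REAL; // coplanar set
  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c, int opposite) {
    Face f{a, b, c, 0,0,0,0, true};
    face_plane(P, f);
    double s = f.nx*P(opposite,0) + f.ny*P(opposite,1) + f.nz*P(opposite,2) - f.d;
    if (s > 0) { std::swap(f.b, f.c); face_plane(P, f); } // outward normal
    faces.push_back(f);
  };
  add_face(i0, i1, i2, i3);
  add_face(i0, i1, i3, i2);
  add_face(i0, i2, i3, i1);
  add_face(i1, i2, i3, i0);
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double s = faces[f].nx*P(p,0) + faces[f].ny*P(p,1) + faces[f].nz*P(p,2) - faces[f].d;
      double nn = std::sqrt(faces[f].nx*faces[f].nx + faces[f].ny*faces[f].ny + faces[f].nz*faces[f].nz);
      if (s > eps * std::max(nn, 1.0)) vis.push_back((int)f);
    }
    if (vis.empty()) continue;
    // horizon edges: edges of visible faces not shared with another visible face
    std::unordered_map<long long, int> edge_count;
    auto ekey = [](int a, int b) {
      int lo = std::min(a,b), hi = std::max(a,b);
      return (long long)lo * 1000003LL + hi;
    };
    for (int f : vis) {
      int e[3][2] = {{faces[f].a, faces[f].b}, {faces[f].b, faces[f].c}, {faces[f].c, faces[f].a}};
      for (auto& ed : e) edge_count[ekey(ed[0], ed[1])]++;
    }
    std::vector<std::array<int,2>> horizon;
    for (int f : vis) {
      int e[3][2] = {{faces[f].a, faces[f].b}, {faces[f].b, faces[f].c}, {faces[f].c, faces[f].a}};
      for (auto& ed : e)
        if (edge_count[ekey(ed[0], ed[1])] == 1) horizon.push_back({{ed[0], ed[1]}});
      faces[f].alive = false;
    }
    for (auto& ed : horizon) {
      Face f{ed[0], ed[1], p, 0,0,0,0, true};
      face_plane(P, f);
      // orient outward: interior reference = centroid of initial tetra
      double cx = (P(i0,0)+P(i1,0)+P(i2,0)+P(i3,0))/4.0;
      double cy = (P(i0,1)+P(i1,1)+P(i2,1)+P(i3,1))/4.0;
      double cz = (P(i0,2)+P(i1,2)+P(i2,2)+P(i3,2))/4.0;
      double s = f.nx*cx + f.ny*cy + f.nz*cz - f.d;
      if (s > 0) { std::swap(f.b, f.c); face_plane(P, f); }
      faces.push_back(f);
    }
  }
  double area = 0;
  for (auto& f : faces)
    if (f.alive)
      area += 0.5 * std::sqrt(f.nx*f.nx + f.ny*f.ny + f.nz*f.nz);
  return area;
}
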