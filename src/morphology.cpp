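// 3D binary-image primitives used by the anatomy and imaging modules:
//  - anisotropic squared Euclidean distance transform (separable lower-envelope)
//  - homotopic curve thinning (distance-ordered removal of simple points)
//  - 26-connected component labelling
// Arrays are passed flattened in R order (first dimension fastest).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const double BIG = 1e30;

// 1D squared distance transform under cost w2*(p-q)^2 + f(q)
// (Felzenszwalb & Huttenlocher lower envelope of parabolas)
static void dt1d(const std::vector<double>& f, double w2, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int vk = v[k];
      s = ((f[q] + w2 * q * q) - (f[vk] + w2 * vk * vk)) / (2.0 * w2 * (q - vk));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const int vk = v[k];
    d[q] = w2 * (q - vk) * (q - vk) + f[vk];
  }
}

// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // distance to nearest background voxel centre; background itself is 0
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;

  std::vector<double> f, d;
  // pass along x
  {
    const double w2 = spacing[0] * spacing[0];
    f.resize(nx); d.resize(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int x = 0; x < nx; ++x) f[x] = out[base + x];
        dt1d(f, w2, d);
        for (int x = 0; x < nx; ++x) out[base + x] = d[x];
      }
  }
  // pass along y
  {
    const double w2 = spacing[1] * spacing[1];
    f.resize(ny); d.resize(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t base = x + (R_xlen_t)nx * ny * (R_xlen_t)z;
        for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
        dt1d(f, w2, d);
        for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
      }
  }
  // pass along z
  {
    const double w2 = spacing[2] * spacing[2];
    f.resize(nz); d.resize(nz);
    const R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t base = x + (R_xlen_t)nx * y;
        for (int z = 0; z < nz; ++z) f[z] = out[base + stride * z];
        dt1d(f, w2, d);
        for (int z = 0; z < nz; ++z) out[base + stride * z] = d[z];
      }
  }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point machinery. Neighbourhood is a 3x3x3 cube indexed
// idx = (dx+1) + 3*(dy+1) + 9*(dz+1); centre is 13.

static inline bool adj26(int a, int b) {
  const int ax = a % 3, ay = (a / 3) % 3, az = a / 9;
  const int bx = b % 3, by = (b / 3) % 3, bz = b / 9;
  const int dx = std::abs(ax - bx), dy = std::abs(ay - by), dz = std::abs(az - bz);
  if (dx > 1 || dy > 1 || dz > 1) return false;
  return (dx + dy + dz) > 0;
}

static inline bool adj6(int a, int b) {
  const int ax = a % 3, ay = (a / 3) % 3, az = a / 9;
  const int bx = b % 3, by = (b / 3) % 3, bz = b / 9;
  return std::abs(ax - bx) + std::abs(ay - by) + std::abs(az - bz) == 1;
}

// number of 26-connected foreground components among the 26 neighbours
static int fgComponents(const bool nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++ncomp;
    std::queue<int> q;
    q.push(i); seen[i] = true;
    while (!q.empty()) {
      const int c = q.front(); q.pop();
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || seen[j] || !nb[j]) continue;
        if (adj26(c, j)) { seen[j] = true; q.push(j); }
      }
    }
  }
  return ncomp;
}

// number of 6-connected background components in the 18-neighbourhood
// that are 6-adjacent to the centre
static int bgComponents(const bool nb[27]) {
  // members of N18: offsets with 1 <= |dx|+|dy|+|dz| <= 2
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    const int ax = (i % 3) - 1, ay = ((i / 3) % 3) - 1, az = (i / 9) - 1;
    const int m = std::abs(ax) + std::abs(ay) + std::abs(az);
    in18[i] = (m >= 1 && m <= 2);
  }
  bool seen[27] = {false};
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || nb[i] || seen[i]) continue;
    if (!adj6(i, 13)) continue;          // seed components only at face neighbours
    ++ncomp;
    std::queue<int> q;
    q.push(i); seen[i] = true;
    while (!q.empty()) {
      const int c = q.front(); q.pop();
      for (int j = 0; j < 27; ++j) {
        if (!in18[j] || seen[j] || nb[j]) continue;
        if (adj6(c, j)) { seen[j] = true; q.push(j); }
      }
    }
  }
  return ncomp;
}

struct Grid {
  const uint8_t* m;
  int nx, ny, nz;
  inline bool at(int x, int y, int z) const {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
    return m[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] != 0;
  }
};

static void fillNb(const Grid& g, int x, int y, int z, bool nb[27]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k)
        nb[k] = g.at(x + dx, y + dy, z + dz);
}

static inline int countFgNb(const bool nb[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
  return c;
}

static inline bool hasBgFaceNb(const bool nb[27]) {
  static const int faces[6] = {4, 10, 12, 14, 16, 22};
  for (int i = 0; i < 6; ++i) if (!nb[faces[i]]) return true;
  return false;
}

static bool isSimple(const bool nb[27]) {
  return fgComponents(nb) == 1 && bgComponents(nb) == 1;
}

// Homotopic curve thinning with six directional subiterations: borders are
// peeled one face direction at a time, and only voxels with background on
// the direction side and foreground on the opposite side qualify (true
// border peeling), which keeps thinning symmetric and stops one-voxel-thick
// structures from zippering away in the degenerate passes. Within a
// subiteration, candidate voxels are deleted sequentially in increasing
// priority order (priority = distance-map value, so the skeleton settles on
// the medial axis) with the simple-point test re-checked at deletion time.
// Curve endpoints (<=1 foreground neighbour) are preserved.
// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dim, NumericVector priority) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<uint8_t> m(n);
  for (R_xlen_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  Grid g{m.data(), nx, ny, nz};

  // face-neighbour offsets: -x, +x, -y, +y, -z, +z
  const int fdx[6] = {-1, 1, 0, 0, 0, 0};
  const int fdy[6] = {0, 0, -1, 1, 0, 0};
  const int fdz[6] = {0, 0, 0, 0, -1, 1};

  std::vector<R_xlen_t> cand;
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            const R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
            if (!m[i]) continue;
            if (g.at(x + fdx[dir], y + fdy[dir], z + fdz[dir])) continue;
            if (!g.at(x - fdx[dir], y - fdy[dir], z - fdz[dir])) continue;
            fillNb(g, x, y, z, nb);
            if (countFgNb(nb) <= 1) continue;   // endpoint or isolated
            if (isSimple(nb)) cand.push_back(i);
          }
      std::stable_sort(cand.begin(), cand.end(),
                       [&](R_xlen_t a, R_xlen_t b) { return priority[a] < priority[b]; });
      for (R_xlen_t idx : cand) {
        if (!m[idx]) continue;
        const int x = (int)(idx % nx);
        const int y = (int)((idx / nx) % ny);
        const int z = (int)(idx / ((R_xlen_t)nx * ny));
        if (g.at(x + fdx[dir], y + fdy[dir], z + fdz[dir])) continue;
        if (!g.at(x - fdx[dir], y - fdy[dir], z - fdz[dir])) continue;
        fillNb(g, x, y, z, nb);
        if (countFgNb(nb) <= 1) continue;
        if (!isSimple(nb)) continue;
        m[idx] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  return out;
}

// [[Rcpp::export]]
IntegerVector label26_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t c = q.front(); q.pop();
      const int x = (int)(c % nx);
      const int y = (int)((c / nx) % ny);
      const int z = (int)(c / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
            const R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[j] && !lab[j]) { lab[j] = next; q.push(j); }
          }
    }
  }
  return lab;
}
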