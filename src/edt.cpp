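#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1-D squared Euclidean distance transform (lower-envelope algorithm of
// Felzenszwalb & Huttenlocher), with physical step size between samples.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s;
    for (;;) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * step;
    d[q] = dx * dx + f[v[k]];
  }
}

// separable squared EDT over a pre-seeded field g (0 at sites, large
// elsewhere)
static void edt3d_core(std::vector<double>& g, const int nx, const int ny,
                       const int nz, const double* spacing) {
  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; ++x) f[x] = g[base + x];
        dt1d(f, d, nx, spacing[0]);
        for (int x = 0; x < nx; ++x) g[base + x] = d[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)y * nx];
        dt1d(f, d, ny, spacing[1]);
        for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    const R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) f[z] = g[base + z * stride];
        dt1d(f, d, nz, spacing[2]);
        for (int z = 0; z < nz; ++z) g[base + z * stride] = d[z];
      }
  }
}

// Euclidean distance (mm) from each voxel centre to the nearest centre of a
// voxel where mask is FALSE. Anisotropic spacing supported.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims,
                    NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // large finite seed (> squared grid diagonal) keeps the lower-envelope
  // parabola intersections finite even along all-inside scan lines
  const double span =
      nx * spacing[0] + ny * spacing[1] + nz * spacing[2];
  const double BIG = span * span;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;
  edt3d_core(g, nx, ny, nz, &spacing[0]);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// Depth below the mask surface with subvoxel accuracy. The surface is
// located at the 0.5 level of the 3x3x3 box-mean coverage of the binary
// mask, sampled where it crosses the lattice lines (exact for planar
// interfaces). Inside voxels whose centre-to-centre EDT is <= band_mm get
// the exact Euclidean distance to the nearest crossing point (bucketed
// ring search); deeper voxels fall back to the centre EDT minus half the
// mean spacing. Outside voxels get 0.
// [[Rcpp::export(name = ".surface_depth")]]
NumericVector surface_depth(LogicalVector mask, IntegerVector dims,
                            NumericVector spacing, double band_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double mean_sp = (sx + sy + sz) / 3.0;
  const double min_sp = std::min(sx, std::min(sy, sz));
  auto idx = [&](int x, int y, int z) {
    return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
  };

  // 3x3x3 box-mean coverage with replicated edges (no artificial surface
  // at the grid border)
  std::vector<double> F(n), tmp(n);
  for (R_xlen_t i = 0; i < n; ++i) F[i] = mask[i] ? 1.0 : 0.0;
  auto clampi = [](int v, int hi) { return v < 0 ? 0 : (v > hi ? hi : v); };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        tmp[idx(x, y, z)] = (F[idx(clampi(x - 1, nx - 1), y, z)] +
                             F[idx(x, y, z)] +
                             F[idx(clampi(x + 1, nx - 1), y, z)]) / 3.0;
  std::swap(F, tmp);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        tmp[idx(x, y, z)] = (F[idx(x, clampi(y - 1, ny - 1), z)] +
                             F[idx(x, y, z)] +
                             F[idx(x, clampi(y + 1, ny - 1), z)]) / 3.0;
  std::swap(F, tmp);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        tmp[idx(x, y, z)] = (F[idx(x, y, clampi(z - 1, nz - 1))] +
                             F[idx(x, y, z)] +
                             F[idx(x, y, clampi(z + 1, nz - 1))]) / 3.0;
  std::swap(F, tmp);

  // crossing points on lattice lines between inside/outside neighbours
  std::vector<double> px, py, pz;
  auto add_crossing = [&](int xa, int ya, int za, int xb, int yb, int zb) {
    R_xlen_t a = idx(xa, ya, za), b = idx(xb, yb, zb);
    if (mask[a] == mask[b]) return;
    double fa = F[a], fb = F[b], t = 0.5;
    if (std::fabs(fb - fa) > 1e-12) t = (0.5 - fa) / (fb - fa);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    px.push_back((xa + t * (xb - xa)) * sx);
    py.push_back((ya + t * (yb - ya)) * sy);
    pz.push_back((za + t * (zb - za)) * sz);
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        // grid borders are treated as body truncation, not surface
        if (x < nx - 1) add_crossing(x, y, z, x + 1, y, z);
        if (y < ny - 1) add_crossing(x, y, z, x, y + 1, z);
        if (z < nz - 1) add_crossing(x, y, z, x, y, z + 1);
      }
  const size_t np = px.size();

  // bucket crossings by the voxel cell containing them
  std::vector<int> cell(np);
  std::vector<int> count(n, 0);
  for (size_t p = 0; p < np; ++p) {
    int cxi = (int)std::floor(px[p] / sx + 0.5);
    int cyi = (int)std::floor(py[p] / sy + 0.5);
    int czi = (int)std::floor(pz[p] / sz + 0.5);
    cxi = std::max(0, std::min(nx - 1, cxi));
    cyi = std::max(0, std::min(ny - 1, cyi));
    czi = std::max(0, std::min(nz - 1, czi));
    cell[p] = (int)idx(cxi, cyi, czi);
    ++count[cell[p]];
  }
  std::vector<R_xlen_t> start(n + 1, 0);
  for (R_xlen_t i = 0; i < n; ++i) start[i + 1] = start[i] + count[i];
  std::vector<int> order(np);
  {
    std::vector<R_xlen_t> cur(start.begin(), start.end() - 1);
    for (size_t p = 0; p < np; ++p) order[cur[cell[p]]++] = (int)p;
  }

  // centre-to-centre EDT for banding and deep fallback
  const double span = nx * sx + ny * sy + nz * sz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? span * span : 0.0;
  edt3d_core(g, nx, ny, nz, &spacing[0]);

  NumericVector out(n);
  const int rmax = (int)std::ceil(band_mm / min_sp) + 2;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx(x, y, z);
        if (!mask[i]) { out[i] = 0.0; continue; }
        double coarse = std::sqrt(g[i]);
        if (coarse > band_mm) {
          out[i] = coarse - 0.5 * mean_sp;
          continue;
        }
        const double vx = x * sx, vy = y * sy, vz = z * sz;
        double best2 = std::numeric_limits<double>::infinity();
        auto scan_cell = [&](int xx, int yy, int zz) {
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
              zz >= nz)
            return;
          R_xlen_t c = idx(xx, yy, zz);
          for (R_xlen_t q = start[c]; q < start[c + 1]; ++q) {
            int p = order[q];
            double ddx = px[p] - vx, ddy = py[p] - vy, ddz = pz[p] - vz;
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 < best2) best2 = d2;
          }
        };
        for (int r = 0; r <= rmax; ++r) {
          double ring_min = (r - 1) * min_sp;
          if (ring_min > 0 && ring_min * ring_min > best2) break;
          if (r == 0) {
            scan_cell(x, y, z);
            continue;
          }
          // enumerate only the faces of the Chebyshev ring
          for (int dy = -r; dy <= r; ++dy)
            for (int dz = -r; dz <= r; ++dz) {
              scan_cell(x - r, y + dy, z + dz);
              scan_cell(x + r, y + dy, z + dz);
            }
          for (int dx = -r + 1; dx <= r - 1; ++dx)
            for (int dz = -r; dz <= r; ++dz) {
              scan_cell(x + dx, y - r, z + dz);
              scan_cell(x + dx, y + r, z + dz);
            }
          for (int dx = -r + 1; dx <= r - 1; ++dx)
            for (int dy = -r + 1; dy <= r - 1; ++dy) {
              scan_cell(x + dx, y + dy, z - r);
              scan_cell(x + dx, y + dy, z + r);
            }
        }
        out[i] = std::isfinite(best2) ? std::sqrt(best2)
                                      : coarse - 0.5 * mean_sp;
      }
  out.attr("dim") = dims;
  return out;
}

// Fill internal cavities of a binary volume: every FALSE voxel not
// 6-connected to the volume border becomes TRUE.
// [[Rcpp::export(name = ".fill_holes3d")]]
LogicalVector fill_holes3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::queue<R_xlen_t> q;

  auto idx = [&](int x, int y, int z) {
    return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
  };
  auto push = [&](int x, int y, int z) {
    R_xlen_t i = idx(x, y, z);
    if (!mask[i] && !outside[i]) {
      outside[i] = 1;
      q.push(i);
    }
  };

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (x == 0 || y == 0 || z == 0 || x == nx - 1 || y == ny - 1 ||
            z == nz - 1)
          push(x, y, z);

  while (!q.empty()) {
    R_xlen_t i = q.front();
    q.pop();
    int z = (int)(i / ((R_xlen_t)nx * ny));
    int rem = (int)(i % ((R_xlen_t)nx * ny));
    int y = rem / nx, x = rem % nx;
    if (x > 0) push(x - 1, y, z);
    if (x < nx - 1) push(x + 1, y, z);
    if (y > 0) push(x, y - 1, z);
    if (y < ny - 1) push(x, y + 1, z);
    if (z > 0) push(x, y, z - 1);
    if (z < nz - 1) push(x, y, z + 1);
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  out.attr("dim") = dims;
  return out;
}

// Number of 6-connected components among TRUE voxels.
// [[Rcpp::export(name = ".count_components3d")]]
int count_components3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  int ncomp = 0;
  std::queue<R_xlen_t> q;
  auto idx = [&](int x, int y, int z) {
    return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
  };
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || seen[s]) continue;
    ++ncomp;
    seen[s] = 1;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t i = q.front();
      q.pop();
      int z = (int)(i / ((R_xlen_t)nx * ny));
      int rem = (int)(i % ((R_xlen_t)nx * ny));
      int y = rem / nx, x = rem % nx;
      auto visit = [&](int xx, int yy, int zz) {
        R_xlen_t j = idx(xx, yy, zz);
        if (mask[j] && !seen[j]) {
          seen[j] = 1;
          q.push(j);
        }
      };
      if (x > 0) visit(x - 1, y, z);
      if (x < nx - 1) visit(x + 1, y, z);
      if (y > 0) visit(x, y - 1, z);
      if (y < ny - 1) visit(x, y + 1, z);
      if (z > 0) visit(x, y, z - 1);
      if (z < nz - 1) visit(x, y, z + 1);
    }
  }
  return ncomp;
}
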