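#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Cell list over 3D points for fixed-radius neighbor queries.
// ---------------------------------------------------------------------------
struct CellList {
  double ox, oy, oz, cell;
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;

  CellList(const NumericMatrix& xyz, double cell_size) : cell(cell_size) {
    const int n = xyz.nrow();
    double inf = std::numeric_limits<double>::infinity();
    ox = oy = oz = inf;
    double mx = -inf, my = -inf, mz = -inf;
    for (int i = 0; i < n; ++i) {
      ox = std::min(ox, xyz(i, 0)); mx = std::max(mx, xyz(i, 0));
      oy = std::min(oy, xyz(i, 1)); my = std::max(my, xyz(i, 1));
      oz = std::min(oz, xyz(i, 2)); mz = std::max(mz, xyz(i, 2));
    }
    if (n == 0) { ox = oy = oz = 0; mx = my = mz = 0; }
    nx = std::max(1, (int)std::floor((mx - ox) / cell) + 1);
    ny = std::max(1, (int)std::floor((my - oy) / cell) + 1);
    nz = std::max(1, (int)std::floor((mz - oz) / cell) + 1);
    cells.resize((size_t)nx * ny * nz);
    for (int i = 0; i < n; ++i)
      cells[index_of(xyz(i, 0), xyz(i, 1), xyz(i, 2))].push_back(i);
  }

  size_t index_of(double x, double y, double z) const {
    int ix = clampi((int)std::floor((x - ox) / cell), nx);
    int iy = clampi((int)std::floor((y - oy) / cell), ny);
    int iz = clampi((int)std::floor((z - oz) / cell), nz);
    return ((size_t)iz * ny + iy) * nx + ix;
  }

  static int clampi(int v, int n) { return v < 0 ? 0 : (v >= n ? n - 1 : v); }

  // collect candidate neighbors in the 27-cell block around (x, y, z)
  void gather(double x, double y, double z, std::vector<int>& out) const {
    out.clear();
    int ix = clampi((int)std::floor((x - ox) / cell), nx);
    int iy = clampi((int)std::floor((y - oy) / cell), ny);
    int iz = clampi((int)std::floor((z - oz) / cell), nz);
    for (int dz = -1; dz <= 1; ++dz) {
      int jz = iz + dz; if (jz < 0 || jz >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int jy = iy + dy; if (jy < 0 || jy >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int jx = ix + dx; if (jx < 0 || jx >= nx) continue;
          const std::vector<int>& c = cells[((size_t)jz * ny + jy) * nx + jx];
          out.insert(out.end(), c.begin(), c.end());
        }
      }
    }
  }
};

// ---------------------------------------------------------------------------
// Shrake-Rupley SASA. xyz: n x 3; radii: vdW radii; sphere: k x 3 unit
// vectors (deterministic point set supplied from R). Returns per-atom area.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_sasa")]]
NumericVector cpp_sasa(const NumericMatrix& xyz, const NumericVector& radii,
                       double probe, const NumericMatrix& sphere) {
  const int n = xyz.nrow(), k = sphere.nrow();
  NumericVector area(n);
  if (n == 0) return area;
  double rmax = 0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  // cell size: largest possible neighbor distance r_i + r_j + 2 probe
  CellList cl(xyz, 2.0 * (rmax + probe));
  std::vector<int> cand;
  std::vector<double> nbx, nby, nbz, nbr2;
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    const double ri = radii[i] + probe;
    cl.gather(xi, yi, zi, cand);
    nbx.clear(); nby.clear(); nbz.clear(); nbr2.clear();
    for (int j : cand) {
      if (j == i) continue;
      const double rj = radii[j] + probe;
      const double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double lim = ri + rj;
      if (d2 < lim * lim) {
        nbx.push_back(xyz(j, 0)); nby.push_back(xyz(j, 1));
        nbz.push_back(xyz(j, 2)); nbr2.push_back(rj * rj);
      }
    }
    int acc = 0;
    const size_t m = nbx.size();
    for (int p = 0; p < k; ++p) {
      const double px = xi + ri * sphere(p, 0);
      const double py = yi + ri * sphere(p, 1);
      const double pz = zi + ri * sphere(p, 2);
      bool exposed = true;
      for (size_t j = 0; j < m; ++j) {
        const double dx = px - nbx[j], dy = py - nby[j], dz = pz - nbz[j];
        if (dx * dx + dy * dy + dz * dz < nbr2[j]) { exposed = false; break; }
      }
      if (exposed) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)k;
  }
  return area;
}

// ---------------------------------------------------------------------------
// All atom pairs (i from set A, j from set B) within cutoff.
// Returns a 3-column matrix: i (1-based into A), j (1-based into B), distance.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_pairs_within")]]
NumericMatrix cpp_pairs_within(const NumericMatrix& a, const NumericMatrix& b,
                               double cutoff) {
  std::vector<double> out;
  if (cutoff > 0 && a.nrow() > 0 && b.nrow() > 0) {
    CellList cl(b, cutoff);
    const double c2 = cutoff * cutoff;
    std::vector<int> cand;
    for (int i = 0; i < a.nrow(); ++i) {
      const double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2);
      cl.gather(xi, yi, zi, cand);
      for (int j : cand) {
        const double dx = b(j, 0) - xi, dy = b(j, 1) - yi, dz = b(j, 2) - zi;
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= c2)
          { out.push_back(i + 1); out.push_back(j + 1); out.push_back(std::sqrt(d2)); }
      }
    }
  }
  NumericMatrix res(out.size() / 3, 3);
  for (size_t r = 0; r < out.size() / 3; ++r)
    for (int c = 0; c < 3; ++c) res(r, c) = out[3 * r + c];
  colnames(res) = CharacterVector::create("i", "j", "distance");
  return res;
}

// ---------------------------------------------------------------------------
// Voxel cavity: mark voxels within atom_radius of any atom as solid, flood
// fill the void component containing the start voxel, then dilate the cavity
// by atom_radius (cavity measured to atom centers). Grid is axis-aligned,
// dims (nx, ny, nz), origin at voxel-center (ox, oy, oz), spacing h.
// Returns c(n_cavity_voxels_after_dilation, leaked, center_solid).
// "leaked" = the fill reached the grid boundary (shell not watertight).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_cavity_fill")]]
NumericVector cpp_cavity_fill(const NumericMatrix& xyz, double atom_radius,
                              double h, const NumericVector& origin,
                              const IntegerVector& dims,
                              const NumericVector& start) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t ntot = (size_t)nx * ny * nz;
  std::vector<uint8_t> solid(ntot, 0);

  // stamp solid voxels atom by atom
  const int rr = (int)std::ceil(atom_radius / h);
  const double r2 = atom_radius * atom_radius;
  for (int i = 0; i < xyz.nrow(); ++i) {
    const int cx = (int)std::round((xyz(i, 0) - origin[0]) / h);
    const int cy = (int)std::round((xyz(i, 1) - origin[1]) / h);
    const int cz = (int)std::round((xyz(i, 2) - origin[2]) / h);
    for (int dz = -rr; dz <= rr; ++dz) {
      const int z = cz + dz; if (z < 0 || z >= nz) continue;
      for (int dy = -rr; dy <= rr; ++dy) {
        const int y = cy + dy; if (y < 0 || y >= ny) continue;
        for (int dx = -rr; dx <= rr; ++dx) {
          const int x = cx + dx; if (x < 0 || x >= nx) continue;
          const double gx = origin[0] + x * h - xyz(i, 0);
          const double gy = origin[1] + y * h - xyz(i, 1);
          const double gz = origin[2] + z * h - xyz(i, 2);
          if (gx * gx + gy * gy + gz * gz <= r2)
            solid[((size_t)z * ny + y) * nx + x] = 1;
        }
      }
    }
  }

  const int sx = (int)std::round((start[0] - origin[0]) / h);
  const int sy = (int)std::round((start[1] - origin[1]) / h);
  const int sz = (int)std::round((start[2] - origin[2]) / h);
  if (sx < 0 || sx >= nx || sy < 0 || sy >= ny || sz < 0 || sz >= nz)
    stop("start voxel outside grid");
  const size_t s0 = ((size_t)sz * ny + sy) * nx + sx;
  if (solid[s0]) return NumericVector::create(0.0, 0.0, 1.0);

  // 6-connected flood fill
  std::vector<uint8_t> cav(ntot, 0);
  std::vector<size_t> stack;
  stack.push_back(s0);
  cav[s0] = 1;
  bool leaked = false;
  while (!stack.empty()) {
    const size_t v = stack.back(); stack.pop_back();
    const int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((size_t)nx * ny));
    if (x == 0 || x == nx - 1 || y == 0 || y == ny - 1 || z == 0 || z == nz - 1)
      leaked = true;
    const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int q = 0; q < 6; ++q) {
      const int X = x + off[q][0], Y = y + off[q][1], Z = z + off[q][2];
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
      const size_t w = ((size_t)Z * ny + Y) * nx + X;
      if (!solid[w] && !cav[w]) { cav[w] = 1; stack.push_back(w); }
    }
  }

  // dilate cavity by atom_radius: cavity is measured to atom centers
  std::vector<uint8_t> dil = cav;
  std::vector<std::array<int,3>> ball;
  for (int dz = -rr; dz <= rr; ++dz)
    for (int dy = -rr; dy <= rr; ++dy)
      for (int dx = -rr; dx <= rr; ++dx) {
        const double d2 = (double)(dx*dx + dy*dy + dz*dz) * h * h;
        if (d2 <= r2 && (dx || dy || dz)) ball.push_back({dx, dy, dz});
      }
  for (size_t v = 0; v < ntot; ++v) {
    if (!cav[v]) continue;
    const int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((size_t)nx * ny));
    // only boundary cavity voxels need stamping
    bool boundary = false;
    const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int q = 0; q < 6 && !boundary; ++q) {
      const int X = x + off[q][0], Y = y + off[q][1], Z = z + off[q][2];
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
      if (!cav[((size_t)Z * ny + Y) * nx + X]) boundary = true;
    }
    if (!boundary) continue;
    for (const auto& d : ball) {
      const int X = x + d[0], Y = y + d[1], Z = z + d[2];
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
      dil[((size_t)Z * ny + Y) * nx + X] = 1;
    }
  }
  double count = 0;
  for (size_t v = 0; v < ntot; ++v) count += dil[v];
  return NumericVector::create(count, leaked ? 1.0 : 0.0, 0.0);
}
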