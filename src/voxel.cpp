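#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---- union-find ---------------------------------------------------------

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Label connected components of a 3D logical mask.
// connectivity: 6 (face) or 26 (face+edge+corner).
// Returns integer array, 0 = background, components numbered 1..n in
// first-voxel order (deterministic).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<int> parent(n);
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

  // neighbour offsets with strictly "previous" linear index to scan once
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 0; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int lin = dx + dy * nx + dz * nx * ny;
        if (lin >= 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x + (R_xlen_t)y * nx + (R_xlen_t)z * nx * ny;
        if (!mask[i]) continue;
        for (auto &o : offs) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          R_xlen_t j = xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * nx * ny;
          if (mask[j]) uf_union(parent, (int)i, (int)j);
        }
      }

  IntegerVector out(n, 0);
  std::vector<int> lab(n, 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int r = uf_find(parent, (int)i);
    if (lab[r] == 0) lab[r] = ++next;
    out[i] = lab[r];
  }
  out.attr("dim") = dim;
  return out;
}

// ---- squared Euclidean distance transform (Felzenszwalb & Huttenlocher) --

static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, int n) {
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= zb[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from every voxel to the nearest
// background (FALSE) voxel centre. Voxels outside the grid are treated as
// background at unit distance beyond the face.
// [[Rcpp::export(name = ".edt3_sq_cpp")]]
NumericVector edt3_sq_cpp(LogicalVector mask, IntegerVector dim,
                          bool pad_background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  const double BIG = 1e20;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz)) + 2;
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (optionally padded with background just outside the grid)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)y * nx + (R_xlen_t)z * nx * ny;
      int m = pad_background ? nx + 2 : nx;
      int off = pad_background ? 1 : 0;
      if (pad_background) { f[0] = 0.0; f[nx + 1] = 0.0; }
      for (int x = 0; x < nx; ++x) f[x + off] = out[base + x];
      dt1d(f, d, v, zb, m);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x + off];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)z * nx * ny;
      int m = pad_background ? ny + 2 : ny;
      int off = pad_background ? 1 : 0;
      if (pad_background) { f[0] = 0.0; f[ny + 1] = 0.0; }
      for (int y = 0; y < ny; ++y) f[y + off] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, v, zb, m);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y + off];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)y * nx;
      int m = pad_background ? nz + 2 : nz;
      int off = pad_background ? 1 : 0;
      if (pad_background) { f[0] = 0.0; f[nz + 1] = 0.0; }
      for (int z = 0; z < nz; ++z) f[z + off] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, v, zb, m);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = d[z + off];
    }
  out.attr("dim") = dim;
  return out;
}

// ---- model-independent local thickness ----------------------------------

// Local thickness in voxel units: for each foreground voxel p, the diameter
// of the largest sphere that lies entirely inside the structure and
// contains p (Hildebrand-Ruegsegger). Spheres are centred on foreground
// voxels with radius r_c = edt(c) - 0.5 (the structure boundary lies half a
// voxel beyond the nearest background voxel centre); a voxel counts as
// contained when its centre lies within half a voxel of the sphere,
// thickness(p) = 2 * max{ r_c : |p - c| <= r_c + 0.5 }.
// [[Rcpp::export(name = ".local_thickness_cpp")]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d2 = edt3_sq_cpp(mask, dim, true);

  struct Center { double r; int x, y, z; };
  std::vector<Center> centers;
  centers.reserve(1024);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = x + (R_xlen_t)y * nx + (R_xlen_t)z * nx * ny;
        if (!mask[i]) continue;
        double r = std::sqrt(d2[i]) - 0.5;
        if (r < 0.5) r = 0.5;  // an isolated voxel is one voxel thick
        centers.push_back({r, x, y, z});
      }
  std::sort(centers.begin(), centers.end(),
            [](const Center &a, const Center &b) { return a.r > b.r; });

  NumericVector out(n, 0.0);
  for (const auto &c : centers) {
    const double r = c.r, diam = 2.0 * r;
    const double rc = r + 0.5, r2 = rc * rc;
    int ri = (int)std::floor(rc);
    for (int dz = -ri; dz <= ri; ++dz) {
      int z = c.z + dz;
      if (z < 0 || z >= nz) continue;
      for (int dy = -ri; dy <= ri; ++dy) {
        int y = c.y + dy;
        if (y < 0 || y >= ny) continue;
        double rem = r2 - (double)dz * dz - (double)dy * dy;
        if (rem < 0) continue;
        int rx = (int)std::floor(std::sqrt(rem));
        int x0 = std::max(0, c.x - rx), x1 = std::min(nx - 1, c.x + rx);
        R_xlen_t base = (R_xlen_t)y * nx + (R_xlen_t)z * nx * ny;
        for (int x = x0; x <= x1; ++x) {
          R_xlen_t i = base + x;
          if (mask[i] && out[i] < diam) out[i] = diam;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
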