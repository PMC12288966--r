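#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 3D index helpers: arrays are column-major with dims (nx, ny, nz);
// a 2D image is passed with nz = 1.

// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, bool full) {
  const int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  int next_label = 0;

  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++next_label;
    labels[seed] = next_label;
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (man == 0) continue;
            if (!full && man != 1) continue; // face connectivity only
            R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[w] && labels[w] == 0) {
              labels[w] = next_label;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return labels;
}

static void blur_axis(std::vector<double>& a, std::vector<double>& tmp,
                      int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double& w : k) w /= s;

  const int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  const R_xlen_t stride = axis == 0 ? 1
    : (axis == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nlines = n / len;

  for (R_xlen_t line = 0; line < nlines; ++line) {
    // base offset of this line
    R_xlen_t base;
    if (axis == 0) {
      base = line * nx;
    } else if (axis == 1) {
      R_xlen_t x = line % nx, z = line / nx;
      base = x + (R_xlen_t)nx * ny * z;
    } else {
      base = line; // (x, y) pairs are contiguous in the first nx*ny entries
    }
    for (int i = 0; i < len; ++i) {
      double acc = 0.0;
      for (int o = -radius; o <= radius; ++o) {
        int j = i + o;
        // reflective boundary (mirror without repeating the edge sample)
        while (j < 0 || j >= len) {
          if (j < 0) j = -j;
          if (j >= len) j = 2 * (len - 1) - j;
        }
        acc += k[o + radius] * a[base + (R_xlen_t)j * stride];
      }
      tmp[i] = acc;
    }
    for (int i = 0; i < len; ++i) a[base + (R_xlen_t)i * stride] = tmp[i];
  }
}

// [[Rcpp::export]]
NumericVector gauss_blur_cpp(NumericVector arr, IntegerVector dims,
                             NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  std::vector<double> a(arr.begin(), arr.end());
  std::vector<double> tmp(std::max(nx, std::max(ny, nz)));
  blur_axis(a, tmp, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(a, tmp, nx, ny, nz, 1, sigma_vox[1]);
  if (nz > 1) blur_axis(a, tmp, nx, ny, nz, 2, sigma_vox.size() > 2 ? sigma_vox[2] : 0.0);
  return NumericVector(a.begin(), a.end());
}

// 1D squared distance transform (lower envelope of parabolas), sample
// spacing h; f holds squared distances on entry and exit. Unreachable
// samples carry a large finite sentinel, which keeps the envelope
// arithmetic finite.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb,
                 int n, double h) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    double s;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (zb[k + 1] < xq) ++k;
    double xv = v[k] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (um^2) from every voxel to the nearest
// background (FALSE) voxel; background voxels get 0. Anisotropic spacing.
// Voxels with no background anywhere return values >= 1e18.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector fg, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double LARGE = 1e18;
  std::vector<double> a(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = fg[i] ? LARGE : 0.0;

  int maxlen = std::max(nx, std::max(ny, nz));
  std::vector<double> f(maxlen), d(maxlen), zb(maxlen + 1);
  std::vector<int> v(maxlen);

  for (int axis = 0; axis < 3; ++axis) {
    const int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
    if (len == 1) continue;
    const double h = spacing[axis];
    const R_xlen_t stride = axis == 0 ? 1
      : (axis == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
    const R_xlen_t nlines = n / len;
    for (R_xlen_t line = 0; line < nlines; ++line) {
      R_xlen_t base;
      if (axis == 0) base = line * nx;
      else if (axis == 1) {
        R_xlen_t x = line % nx, z = line / nx;
        base = x + (R_xlen_t)nx * ny * z;
      } else base = line;
      bool any_pos = false;
      for (int i = 0; i < len; ++i) {
        f[i] = a[base + (R_xlen_t)i * stride];
        if (f[i] > 0.0) any_pos = true;
      }
      if (!any_pos) continue; // all zero: nothing can shrink
      dt1d(f, d, v, zb, len, h);
      for (int i = 0; i < len; ++i) a[base + (R_xlen_t)i * stride] = f[i];
    }
  }
  return NumericVector(a.begin(), a.end());
}
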