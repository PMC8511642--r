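#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Kernel values come from a lookup table sampled uniformly on [0, J/2]
// (linear interpolation): evaluating the Kaiser-Bessel I0 directly per
// weight would dominate the transform cost.
static inline double kb_lookup(double u, const double *tab, int ntab,
                               double half) {
  double a = std::fabs(u);
  if (a >= half) return 0.0;
  double p = a * (ntab - 1) / half;
  int i = (int)p;
  double f = p - i;
  return tab[i] * (1.0 - f) + tab[i + 1] * f;
}

static inline int wrap_index(int f, int Mo) {
  int p = f % Mo;
  if (p < 0) p += Mo;
  return p;
}

// Per-axis neighbor indices and kernel weights for one sample coordinate.
static inline int axis_weights(double kc, int Mo, int J, const double *tab,
                               int ntab, int *idx, double *w) {
  double half = J / 2.0;
  int f0 = (int)std::ceil(kc - half);
  int f1 = (int)std::floor(kc + half);
  int n = 0;
  for (int f = f0; f <= f1; ++f) {
    double wt = kb_lookup(kc - f, tab, ntab, half);
    if (wt != 0.0) {
      idx[n] = wrap_index(f, Mo);
      w[n] = wt;
      ++n;
    }
  }
  return n;
}

// Interpolate an FFT-ordered oversampled Cartesian k-space grid (Mo^3,
// column-major) at non-integer centered frequencies k (n x 3, oversampled
// grid units). Exact adjoint of cpp_kb_spread.
// [[Rcpp::export]]
ComplexVector cpp_kb_interp(ComplexVector grid, NumericMatrix k,
                            int Mo, int J, NumericVector table) {
  int n = k.nrow();
  int ntab = table.size();
  const double *tab = table.begin();
  ComplexVector out(n);
  std::vector<int> ix(J + 2), iy(J + 2), iz(J + 2);
  std::vector<double> wx(J + 2), wy(J + 2), wz(J + 2);
  for (int j = 0; j < n; ++j) {
    int nxw = axis_weights(k(j, 0), Mo, J, tab, ntab, ix.data(), wx.data());
    int nyw = axis_weights(k(j, 1), Mo, J, tab, ntab, iy.data(), wy.data());
    int nzw = axis_weights(k(j, 2), Mo, J, tab, ntab, iz.data(), wz.data());
    double accr = 0.0, acci = 0.0;
    for (int c = 0; c < nzw; ++c) {
      R_xlen_t basez = (R_xlen_t)Mo * Mo * iz[c];
      for (int b = 0; b < nyw; ++b) {
        double wyz = wy[b] * wz[c];
        R_xlen_t base = basez + (R_xlen_t)Mo * iy[b];
        for (int a = 0; a < nxw; ++a) {
          double w = wx[a] * wyz;
          Rcomplex g = grid[base + ix[a]];
          accr += w * g.r;
          acci += w * g.i;
        }
      }
    }
    out[j].r = accr;
    out[j].i = acci;
  }
  return out;
}

// Spread samples y at centered frequencies k onto an FFT-ordered
// oversampled grid (Mo^3). Exact adjoint of cpp_kb_interp.
// [[Rcpp::export]]
ComplexVector cpp_kb_spread(ComplexVector y, NumericMatrix k,
                            int Mo, int J, NumericVector table) {
  int n = k.nrow();
  int ntab = table.size();
  const double *tab = table.begin();
  R_xlen_t ntot = (R_xlen_t)Mo * Mo * Mo;
  ComplexVector grid(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) { grid[i].r = 0.0; grid[i].i = 0.0; }
  std::vector<int> ix(J + 2), iy(J + 2), iz(J + 2);
  std::vector<double> wx(J + 2), wy(J + 2), wz(J + 2);
  for (int j = 0; j < n; ++j) {
    int nxw = axis_weights(k(j, 0), Mo, J, tab, ntab, ix.data(), wx.data());
    int nyw = axis_weights(k(j, 1), Mo, J, tab, ntab, iy.data(), wy.data());
    int nzw = axis_weights(k(j, 2), Mo, J, tab, ntab, iz.data(), wz.data());
    double yr = y[j].r, yi = y[j].i;
    for (int c = 0; c < nzw; ++c) {
      R_xlen_t basez = (R_xlen_t)Mo * Mo * iz[c];
      for (int b = 0; b < nyw; ++b) {
        double wyz = wy[b] * wz[c];
        R_xlen_t base = basez + (R_xlen_t)Mo * iy[b];
        for (int a = 0; a < nxw; ++a) {
          double w = wx[a] * wyz;
          R_xlen_t idx = base + ix[a];
          grid[idx].r += w * yr;
          grid[idx].i += w * yi;
        }
      }
    }
  }
  return grid;
}

// Trilinear interpolation of a real volume at fractional 0-based voxel
// coordinates; coordinates are clamped to the volume boundary.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    double x = pts(j, 0), y = pts(j, 1), z = pts(j, 2);
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
    int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
    if (ix > nx - 2) ix = nx - 2; if (ix < 0) ix = 0;
    if (iy > ny - 2) iy = ny - 2; if (iy < 0) iy = 0;
    if (iz > nz - 2) iz = nz - 2; if (iz < 0) iz = 0;
    double fx = x - ix, fy = y - iy, fz = z - iz;
    int dx = 1, dy = nx;
    R_xlen_t sxy = (R_xlen_t)nx * ny, dz = sxy;
    if (nx == 1) { ix = 0; fx = 0.0; dx = 0; }
    if (ny == 1) { iy = 0; fy = 0.0; dy = 0; }
    if (nz == 1) { iz = 0; fz = 0.0; dz = 0; }
    R_xlen_t i000 = ix + (R_xlen_t)nx * iy + sxy * iz;
    out[j] =
      vol[i000] * (1 - fx) * (1 - fy) * (1 - fz) +
      vol[i000 + dx] * fx * (1 - fy) * (1 - fz) +
      vol[i000 + dy] * (1 - fx) * fy * (1 - fz) +
      vol[i000 + dx + dy] * fx * fy * (1 - fz) +
      vol[i000 + dz] * (1 - fx) * (1 - fy) * fz +
      vol[i000 + dx + dz] * fx * (1 - fy) * fz +
      vol[i000 + dy + dz] * (1 - fx) * fy * fz +
      vol[i000 + dx + dy + dz] * fx * fy * fz;
  }
  return out;
}
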