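#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

// Exact Euclidean distance transform, separable lower-envelope algorithm
// (Felzenszwalb & Huttenlocher), extended to anisotropic voxel spacing.
// Operates on squared distances; one 1-D pass per axis.

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform along a line with physical spacing `h`.
// f: input squared distances at the n sample sites; d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double h, std::vector<int>& v, std::vector<double>& z) {
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { // no finite parabola on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue; // infinite parabolas never enter the envelope
    double xq = q * h;
    double s;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (s <= z[k]) --k; else break; // s is finite, so k stays >= 0
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
Rcpp::NumericVector edt3d_cpp(Rcpp::LogicalVector mask,
                              Rcpp::IntegerVector dims,
                              Rcpp::NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::NumericVector out(n);

  // 0 on feature voxels, +inf elsewhere
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (mask[i] == TRUE) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, nx, hx, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }

  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, ny, hy, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }

  // pass along z
  const R_xlen_t stride = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + k * stride];
      dt1d(f, d, nz, hz, v, z);
      for (int k = 0; k < nz; ++k) out[base + k * stride] = d[k];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] == INF) ? R_PosInf : std::sqrt(out[i]);
  return out;
}
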