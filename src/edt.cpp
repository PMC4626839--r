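#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (lower envelope of parabolas), grid step h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double h) {
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; continue; }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  if (f[v[0]] == INF) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = h2 * dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel to the nearest TRUE voxel
// centre, with anisotropic spacing; INF where the mask is empty.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t off = (size_t)nx * (j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = g[off + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) g[off + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t off = (size_t)i + (size_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = g[off + (size_t)nx * j];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) g[off + (size_t)nx * j] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t off = (size_t)i + (size_t)nx * j;
      size_t stride = (size_t)nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = g[off + stride * k];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) g[off + stride * k] = d[k];
    }

  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  return out;
}
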