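#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// One-dimensional squared distance transform with physical sample spacing s,
// lower-envelope-of-parabolas method (Felzenszwalb & Huttenlocher). Handles
// +Inf inputs (no feature on the line) by skipping their parabolas.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double s) {
  int k = -1;
  double sint = 0.0;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * s;
    while (k >= 0) {
      double xv = v[k] * s;
      sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (sint <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : sint;
    z[k + 1] = INF;
  }
  if (k < 0) {           // no feature voxel anywhere on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[j + 1] < xq) ++j;
    double dx = xq - v[j] * s;
    d[q] = dx * dx + f[v[j]];
  }
}

// Exact Euclidean distance (mm) from every voxel centre to the nearest
// feature voxel centre, on an anisotropic grid. `mask` is a 3D 0/1 array
// (column-major, dims d1 x d2 x d3); `spacing` gives the physical step along
// each array dimension. Voxels with no feature anywhere return Inf.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, NumericVector spacing) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("cpp_edt expects a 3D array");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] != 0 ? 0.0 : INF;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along dim 1 (stride 1)
  for (int k3 = 0; k3 < d3; ++k3)
    for (int k2 = 0; k2 < d2; ++k2) {
      R_xlen_t base = (R_xlen_t)d1 * (k2 + (R_xlen_t)d2 * k3);
      for (int q = 0; q < d1; ++q) f[q] = out[base + q];
      dt1d(f, d, v, z, d1, spacing[0]);
      for (int q = 0; q < d1; ++q) out[base + q] = d[q];
    }
  // pass along dim 2 (stride d1)
  for (int k3 = 0; k3 < d3; ++k3)
    for (int k1 = 0; k1 < d1; ++k1) {
      R_xlen_t base = k1 + (R_xlen_t)d1 * d2 * k3;
      for (int q = 0; q < d2; ++q) f[q] = out[base + (R_xlen_t)q * d1];
      dt1d(f, d, v, z, d2, spacing[1]);
      for (int q = 0; q < d2; ++q) out[base + (R_xlen_t)q * d1] = d[q];
    }
  // pass along dim 3 (stride d1*d2)
  const R_xlen_t s3 = (R_xlen_t)d1 * d2;
  for (int k2 = 0; k2 < d2; ++k2)
    for (int k1 = 0; k1 < d1; ++k1) {
      R_xlen_t base = k1 + (R_xlen_t)d1 * k2;
      for (int q = 0; q < d3; ++q) f[q] = out[base + (R_xlen_t)q * s3];
      dt1d(f, d, v, z, d3, spacing[2]);
      for (int q = 0; q < d3; ++q) out[base + (R_xlen_t)q * s3] = d[q];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] != INF) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}
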