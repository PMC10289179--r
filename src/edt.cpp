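// Exact 3D Euclidean distance transform (squared-distance lower envelope,
// separable pass per axis). Distances are from foreground voxels to the
// nearest background voxel; background voxels are 0. Optionally the volume
// border is treated as adjacent to background so the transform stays finite
// on all-foreground inputs.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double EDT_INF = 1e30;

// 1D squared-distance transform of sampled function f (Felzenszwalb & Huttenlocher)
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_INF;
  z[1] = EDT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector fg, IntegerVector dims, bool border_background) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; i++) d[i] = fg[i] ? EDT_INF : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest-varying)
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      for (int i = 0; i < n1; i++) f[i] = d[base + i];
      dt1d(f, out, n1, v, z);
      for (int i = 0; i < n1; i++) d[base + i] = out[i];
    }
  // axis 2
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; j++) f[j] = d[base + (R_xlen_t)j * n1];
      dt1d(f, out, n2, v, z);
      for (int j = 0; j < n2; j++) d[base + (R_xlen_t)j * n1] = out[j];
    }
  // axis 3
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = (R_xlen_t)j * n1 + i;
      for (int k = 0; k < n3; k++) f[k] = d[base + (R_xlen_t)k * n1 * n2];
      dt1d(f, out, n3, v, z);
      for (int k = 0; k < n3; k++) d[base + (R_xlen_t)k * n1 * n2] = out[k];
    }

  NumericVector res(n);
  R_xlen_t idx = 0;
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++, idx++) {
        double dd = d[idx];
        if (border_background && fg[idx]) {
          // nearest point of the virtual background shell is axis-aligned
          int b = std::min(std::min(i + 1, n1 - i), std::min(std::min(j + 1, n2 - j),
                  std::min(k + 1, n3 - k)));
          double b2 = (double)b * b;
          if (b2 < dd) dd = b2;
        }
        res[idx] = (dd >= EDT_INF) ? R_PosInf : std::sqrt(dd);
      }
  return res;
}
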