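// Separable correlation along one axis with symmetric (edge-duplicating)
// reflection at the borders, and a closed-form symmetric 3x3 eigen-solver
// for per-voxel Hessian matrices.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric reflection with edge duplication: -1 -> 0, n -> n-1
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// kernel is centered: length 2h+1, out[i] = sum_t kern[t+h] * in[i+t]
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int klen = kernel.size();
  const int h = (klen - 1) / 2;
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);

  int nax = (axis == 1) ? n1 : (axis == 2) ? n2 : n3;
  R_xlen_t stride = (axis == 1) ? 1 : (axis == 2) ? (R_xlen_t)n1 : (R_xlen_t)n1 * n2;

  std::vector<double> line(nax), res(nax);
  int no1, no2;  // extents of the two non-axis dimensions
  R_xlen_t so1, so2;
  if (axis == 1)      { no1 = n2; so1 = n1; no2 = n3; so2 = (R_xlen_t)n1 * n2; }
  else if (axis == 2) { no1 = n1; so1 = 1;  no2 = n3; so2 = (R_xlen_t)n1 * n2; }
  else                { no1 = n1; so1 = 1;  no2 = n2; so2 = (R_xlen_t)n1; }

  for (int b = 0; b < no2; b++)
    for (int a = 0; a < no1; a++) {
      R_xlen_t base = (R_xlen_t)a * so1 + (R_xlen_t)b * so2;
      for (int i = 0; i < nax; i++) line[i] = vol[base + (R_xlen_t)i * stride];
      for (int i = 0; i < nax; i++) {
        double acc = 0.0;
        for (int t = -h; t <= h; t++)
          acc += kernel[t + h] * line[reflect_idx(i + t, nax)];
        res[i] = acc;
      }
      for (int i = 0; i < nax; i++) out[base + (R_xlen_t)i * stride] = res[i];
    }
  return out;
}

static inline double cubic(double l, double tr, double m2, double det) {
  // characteristic polynomial det(A - l I) = -l^3 + tr l^2 - m2 l + det
  return ((-l + tr) * l - m2) * l + det;
}
static inline double cubic_d(double l, double tr, double m2) {
  return (-3.0 * l + 2.0 * tr) * l - m2;
}

// Eigenvalues of symmetric 3x3 matrices, sorted by increasing |lambda|.
// Trigonometric closed form plus two Newton polish steps on the
// characteristic polynomial.
// [[Rcpp::export]]
List eig3_sym_cpp(NumericVector hxx, NumericVector hyy, NumericVector hzz,
                  NumericVector hxy, NumericVector hxz, NumericVector hyz) {
  const R_xlen_t n = hxx.size();
  NumericVector l1(n), l2(n), l3(n);
  for (R_xlen_t i = 0; i < n; i++) {
    double a11 = hxx[i], a22 = hyy[i], a33 = hzz[i];
    double a12 = hxy[i], a13 = hxz[i], a23 = hyz[i];
    double e[3];
    double p1 = a12 * a12 + a13 * a13 + a23 * a23;
    if (p1 == 0.0) {
      e[0] = a11; e[1] = a22; e[2] = a33;
    } else {
      double q = (a11 + a22 + a33) / 3.0;
      double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                  (a33 - q) * (a33 - q) + 2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
      double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
      double detB = b11 * (b22 * b33 - b23 * b23) -
                    b12 * (b12 * b33 - b23 * b13) +
                    b13 * (b12 * b23 - b22 * b13);
      double r = detB / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      e[0] = q + 2.0 * p * std::cos(phi);
      e[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e[1] = 3.0 * q - e[0] - e[2];
      // Newton polish on the characteristic polynomial
      double tr = a11 + a22 + a33;
      double m2 = a11 * a22 + a11 * a33 + a22 * a33 -
                  a12 * a12 - a13 * a13 - a23 * a23;
      double det = a11 * (a22 * a33 - a23 * a23) -
                   a12 * (a12 * a33 - a23 * a13) +
                   a13 * (a12 * a23 - a22 * a13);
      for (int k = 0; k < 3; k++) {
        for (int it = 0; it < 2; it++) {
          double dp = cubic_d(e[k], tr, m2);
          if (std::fabs(dp) > 1e-12) {
            double step = cubic(e[k], tr, m2, det) / dp;
            if (std::isfinite(step)) e[k] -= step;
          }
        }
      }
    }
    // sort by absolute value
    double a0 = std::fabs(e[0]), a1 = std::fabs(e[1]), a2 = std::fabs(e[2]);
    if (a0 > a1) { std::swap(e[0], e[1]); std::swap(a0, a1); }
    if (a1 > a2) { std::swap(e[1], e[2]); std::swap(a1, a2); }
    if (a0 > a1) { std::swap(e[0], e[1]); std::swap(a0, a1); }
    l1[i] = e[0]; l2[i] = e[1]; l3[i] = e[2];
  }
  return List::create(Named("l1") = l1, Named("l2") = l2, Named("l3") = l3);
}
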