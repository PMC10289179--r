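// Connected-component labeling, seed-shell statistics and layer-synchronous
// seeded region growing on 3D grids. Connectivity codes: 6, 18, 26, or 8
// (8-neighborhood restricted to the XY plane of each slice; axis 1 is z).
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

struct Offsets {
  std::vector<int> dz, dy, dx;
};

// dims are (n1=z, n2=y, n3=x); linear index = z + n1*y + n1*n2*x
static Offsets make_offsets(int conn) {
  Offsets o;
  for (int dx = -1; dx <= 1; dx++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dz = -1; dz <= 1; dz++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        bool keep = false;
        if (conn == 6) keep = (nz == 1);
        else if (conn == 18) keep = (nz <= 2);
        else if (conn == 26) keep = true;
        else if (conn == 8) keep = (dz == 0);  // in-plane 8-neighborhood
        if (keep) { o.dz.push_back(dz); o.dy.push_back(dy); o.dx.push_back(dx); }
      }
  return o;
}

// [[Rcpp::export]]
List label_components_cpp(LogicalVector mask, IntegerVector dims, int conn) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  Offsets off = make_offsets(conn);
  const int m = off.dz.size();
  IntegerVector lab(n, 0);
  int k = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    k++;
    lab[s] = k;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int z = (int)(v % n1), y = (int)((v / n1) % n2), x = (int)(v / ((R_xlen_t)n1 * n2));
      for (int t = 0; t < m; t++) {
        int zz = z + off.dz[t], yy = y + off.dy[t], xx = x + off.dx[t];
        if (zz < 0 || zz >= n1 || yy < 0 || yy >= n2 || xx < 0 || xx >= n3) continue;
        R_xlen_t w = zz + (R_xlen_t)n1 * yy + (R_xlen_t)n1 * n2 * xx;
        if (mask[w] && lab[w] == 0) { lab[w] = k; stack.push_back(w); }
      }
    }
  }
  return List::create(Named("labels") = lab, Named("n_components") = k);
}

// Mean probability over the shell of each component: the union of the
// (2r+1)^3-minus-center Chebyshev neighborhoods of its voxels, excluding
// every seed voxel (of any component).
// [[Rcpp::export]]
List shell_means_cpp(NumericVector prob, IntegerVector labels, IntegerVector dims,
                     int n_components, int radius) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector sums(n_components), means(n_components);
  IntegerVector counts(n_components);
  LogicalVector shell(n, false);
  std::vector<int> stamp(n, 0);
  // voxel lists per component
  std::vector<std::vector<R_xlen_t> > vox(n_components);
  for (R_xlen_t i = 0; i < n; i++)
    if (labels[i] > 0) vox[labels[i] - 1].push_back(i);
  for (int c = 0; c < n_components; c++) {
    double s = 0.0; int cnt = 0;
    for (size_t q = 0; q < vox[c].size(); q++) {
      R_xlen_t v = vox[c][q];
      int z = (int)(v % n1), y = (int)((v / n1) % n2), x = (int)(v / ((R_xlen_t)n1 * n2));
      for (int dx = -radius; dx <= radius; dx++)
        for (int dy = -radius; dy <= radius; dy++)
          for (int dz = -radius; dz <= radius; dz++) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= n1 || yy < 0 || yy >= n2 || xx < 0 || xx >= n3) continue;
            R_xlen_t w = zz + (R_xlen_t)n1 * yy + (R_xlen_t)n1 * n2 * xx;
            if (labels[w] > 0 || stamp[w] == c + 1) continue;
            stamp[w] = c + 1;
            shell[w] = true;
            s += prob[w];
            cnt++;
          }
    }
    sums[c] = s;
    counts[c] = cnt;
    means[c] = (cnt > 0) ? s / cnt : NA_REAL;
  }
  return List::create(Named("mean") = means, Named("count") = counts,
                      Named("shell") = shell);
}

// Layer-synchronous growth: in each round every unlabeled voxel adjacent to
// the current region joins iff its probability strictly exceeds rho of an
// adjacent component; conflicts resolve to the smallest rho, then smallest
// label, making the result independent of frontier traversal order.
// [[Rcpp::export]]
List region_grow_cpp(NumericVector prob, IntegerVector seed_labels, IntegerVector dims,
                     NumericVector rho, int conn, int max_iters, bool single_step) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  Offsets off = make_offsets(conn);
  const int m = off.dz.size();
  IntegerVector lab = clone(seed_labels);
  std::vector<R_xlen_t> frontier;
  for (R_xlen_t i = 0; i < n; i++) if (lab[i] > 0) frontier.push_back(i);
  std::vector<int> best(n, 0);  // per-round candidate label (0 = none)
  std::vector<R_xlen_t> touched;
  bool truncated = false;
  int iters = 0;
  int limit = single_step ? 1 : max_iters;
  while (!frontier.empty() && iters < limit) {
    touched.clear();
    for (size_t q = 0; q < frontier.size(); q++) {
      R_xlen_t v = frontier[q];
      int c = lab[v];
      double r = rho[c - 1];
      int z = (int)(v % n1), y = (int)((v / n1) % n2), x = (int)(v / ((R_xlen_t)n1 * n2));
      for (int t = 0; t < m; t++) {
        int zz = z + off.dz[t], yy = y + off.dy[t], xx = x + off.dx[t];
        if (zz < 0 || zz >= n1 || yy < 0 || yy >= n2 || xx < 0 || xx >= n3) continue;
        R_xlen_t w = zz + (R_xlen_t)n1 * yy + (R_xlen_t)n1 * n2 * xx;
        if (lab[w] > 0) continue;
        if (!(prob[w] > r)) continue;
        if (best[w] == 0) { best[w] = c; touched.push_back(w); }
        else {
          int bc = best[w];
          if (rho[c - 1] < rho[bc - 1] || (rho[c - 1] == rho[bc - 1] && c < bc))
            best[w] = c;
        }
      }
    }
    frontier.clear();
    for (size_t q = 0; q < touched.size(); q++) {
      R_xlen_t w = touched[q];
      lab[w] = best[w];
      best[w] = 0;
      frontier.push_back(w);
    }
    iters++;
  }
  if (!frontier.empty() && !single_step && iters >= max_iters) truncated = true;
  return List::create(Named("labels") = lab, Named("iterations") = iters,
                      Named("truncated") = truncated);
}
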