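// Compact volumetric residual encoder-decoder with a two-channel SoftMax
// head, written as explicit im2col/BLAS forward-backward passes so training
// is deterministic and dependency-free. One pooling level; 3x3x3 kernels
// with zero padding; nearest-neighbour upsampling; additive skip connection.
//
// Tensors are (channels x voxels) matrices over a (n1, n2, n3) grid with
// linear index i = z + n1*y + n1*n2*x (axis 1 fastest, matching R arrays).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

struct Grid { int n1, n2, n3; R_xlen_t n() const { return (R_xlen_t)n1 * n2 * n3; } };

static void im2col(const mat& X, const Grid& g, mat& P) {
  const int Cin = X.n_rows;
  P.zeros(27 * Cin, g.n());
  const double* xs = X.memptr();
  double* ps = P.memptr();
  const int PR = 27 * Cin;
  int t = 0;
  for (int dx = -1; dx <= 1; dx++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dz = -1; dz <= 1; dz++, t++) {
        for (int x = 0; x < g.n3; x++) {
          int xx = x + dx;
          if (xx < 0 || xx >= g.n3) continue;
          for (int y = 0; y < g.n2; y++) {
            int yy = y + dy;
            if (yy < 0 || yy >= g.n2) continue;
            int z0 = std::max(0, -dz), z1 = std::min(g.n1, g.n1 - dz);
            R_xlen_t dst = (R_xlen_t)g.n1 * (y + (R_xlen_t)g.n2 * x);
            R_xlen_t src = (R_xlen_t)g.n1 * (yy + (R_xlen_t)g.n2 * xx);
            for (int z = z0; z < z1; z++) {
              const double* sc = xs + (src + z + dz) * Cin;
              double* pc = ps + (dst + z) * PR + t * Cin;
              for (int c = 0; c < Cin; c++) pc[c] = sc[c];
            }
          }
        }
      }
}

// adjoint of im2col: scatter-add rows of D (27*Cin x N) back onto the grid
static void col2im(const mat& D, const Grid& g, mat& out, int Cin) {
  out.zeros(Cin, g.n());
  int t = 0;
  for (int dx = -1; dx <= 1; dx++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dz = -1; dz <= 1; dz++, t++) {
        for (int x = 0; x < g.n3; x++) {
          int xx = x + dx;
          if (xx < 0 || xx >= g.n3) continue;
          for (int y = 0; y < g.n2; y++) {
            int yy = y + dy;
            if (yy < 0 || yy >= g.n2) continue;
            int z0 = std::max(0, -dz), z1 = std::min(g.n1, g.n1 - dz);
            R_xlen_t dst = (R_xlen_t)g.n1 * (y + (R_xlen_t)g.n2 * x);
            R_xlen_t src = (R_xlen_t)g.n1 * (yy + (R_xlen_t)g.n2 * xx);
            for (int z = z0; z < z1; z++) {
              const double* dc = D.memptr() + (dst + z) * (R_xlen_t)(27 * Cin) + t * Cin;
              double* oc = out.memptr() + (src + z + dz) * (R_xlen_t)Cin;
              for (int c = 0; c < Cin; c++) oc[c] += dc[c];
            }
          }
        }
      }
}

static mat conv_fwd(const mat& W, const vec& b, const mat& X, const Grid& g) {
  mat P;
  im2col(X, g, P);
  mat out = W * P;
  out.each_col() += b;
  return out;
}

static mat avgpool2(const mat& X, const Grid& g, Grid& h) {
  h.n1 = g.n1 / 2; h.n2 = g.n2 / 2; h.n3 = g.n3 / 2;
  mat out(X.n_rows, h.n());
  for (int x = 0; x < h.n3; x++)
    for (int y = 0; y < h.n2; y++)
      for (int z = 0; z < h.n1; z++) {
        R_xlen_t o = z + (R_xlen_t)h.n1 * (y + (R_xlen_t)h.n2 * x);
        vec acc(X.n_rows, arma::fill::zeros);
        for (int a = 0; a < 2; a++)
          for (int b2 = 0; b2 < 2; b2++)
            for (int c = 0; c < 2; c++) {
              R_xlen_t s = (2 * z + c) +
                (R_xlen_t)g.n1 * ((2 * y + b2) + (R_xlen_t)g.n2 * (2 * x + a));
              acc += X.col(s);
            }
        out.col(o) = acc / 8.0;
      }
  return out;
}

static mat unpool_spread(const mat& D, const Grid& h, const Grid& g, double scale) {
  mat out(D.n_rows, g.n());
  for (int x = 0; x < h.n3; x++)
    for (int y = 0; y < h.n2; y++)
      for (int z = 0; z < h.n1; z++) {
        R_xlen_t o = z + (R_xlen_t)h.n1 * (y + (R_xlen_t)h.n2 * x);
        for (int a = 0; a < 2; a++)
          for (int b2 = 0; b2 < 2; b2++)
            for (int c = 0; c < 2; c++) {
              R_xlen_t s = (2 * z + c) +
                (R_xlen_t)g.n1 * ((2 * y + b2) + (R_xlen_t)g.n2 * (2 * x + a));
              out.col(s) = D.col(o) * scale;
            }
      }
  return out;
}

static mat pool_sum(const mat& D, const Grid& g, const Grid& h) {
  mat out(D.n_rows, h.n(), arma::fill::zeros);
  for (int x = 0; x < h.n3; x++)
    for (int y = 0; y < h.n2; y++)
      for (int z = 0; z < h.n1; z++) {
        R_xlen_t o = z + (R_xlen_t)h.n1 * (y + (R_xlen_t)h.n2 * x);
        for (int a = 0; a < 2; a++)
          for (int b2 = 0; b2 < 2; b2++)
            for (int c = 0; c < 2; c++) {
              R_xlen_t s = (2 * z + c) +
                (R_xlen_t)g.n1 * ((2 * y + b2) + (R_xlen_t)g.n2 * (2 * x + a));
              out.col(o) += D.col(s);
            }
      }
  return out;
}

static inline mat relu(const mat& X) { return arma::clamp(X, 0.0, arma::datum::inf); }

struct Cache {
  Grid g, h;
  mat x0, a_in, h1a, r1, pd, a_d, h2a, r2, us, u, s, h3a, r3, z, p;
};

static void forward(const List& W, const vec& x, const Grid& g, Cache& C) {
  C.g = g;
  C.x0 = mat(1, g.n());
  C.x0.row(0) = x.t();
  mat w_in = W["w_in"];   vec b_in = W["b_in"];
  mat w_r1a = W["w_r1a"]; vec b_r1a = W["b_r1a"];
  mat w_r1b = W["w_r1b"]; vec b_r1b = W["b_r1b"];
  mat w_d = W["w_d"];     vec b_d = W["b_d"];
  mat w_r2a = W["w_r2a"]; vec b_r2a = W["b_r2a"];
  mat w_r2b = W["w_r2b"]; vec b_r2b = W["b_r2b"];
  mat w_up = W["w_up"];   vec b_up = W["b_up"];
  mat w_r3a = W["w_r3a"]; vec b_r3a = W["b_r3a"];
  mat w_r3b = W["w_r3b"]; vec b_r3b = W["b_r3b"];
  mat w_head = W["w_head"]; vec b_head = W["b_head"];

  C.a_in = relu(conv_fwd(w_in, b_in, C.x0, g));
  C.h1a = relu(conv_fwd(w_r1a, b_r1a, C.a_in, g));
  C.r1 = relu(C.a_in + conv_fwd(w_r1b, b_r1b, C.h1a, g));
  C.pd = avgpool2(C.r1, g, C.h);
  C.a_d = relu(conv_fwd(w_d, b_d, C.pd, C.h));
  C.h2a = relu(conv_fwd(w_r2a, b_r2a, C.a_d, C.h));
  C.r2 = relu(C.a_d + conv_fwd(w_r2b, b_r2b, C.h2a, C.h));
  C.us = unpool_spread(C.r2, C.h, g, 1.0);
  C.u = relu(conv_fwd(w_up, b_up, C.us, g));
  C.s = C.u + C.r1;
  C.h3a = relu(conv_fwd(w_r3a, b_r3a, C.s, g));
  C.r3 = relu(C.s + conv_fwd(w_r3b, b_r3b, C.h3a, g));
  C.z = conv_fwd(w_head, b_head, C.r3, g);
  // stable two-class softmax, foreground = channel 2
  rowvec d = C.z.row(1) - C.z.row(0);
  C.p = mat(1, g.n());
  for (R_xlen_t i = 0; i < (R_xlen_t)g.n(); i++) {
    double dd = d(i);
    C.p(0, i) = (dd >= 0.0) ? 1.0 / (1.0 + std::exp(-dd))
                            : std::exp(dd) / (1.0 + std::exp(dd));
  }
}

// [[Rcpp::export]]
NumericVector net_forward_cpp(List weights, NumericVector x, IntegerVector dims) {
  Grid g; g.n1 = dims[0]; g.n2 = dims[1]; g.n3 = dims[2];
  Cache C;
  forward(weights, vec(x.begin(), x.size()), g, C);
  return NumericVector(C.p.begin(), C.p.end());
}

static void conv_bwd(const mat& W, const mat& input, const Grid& g, const mat& dOut,
                     mat& dW, vec& db, mat& dX, bool need_dx) {
  mat P;
  im2col(input, g, P);
  dW = dOut * P.t();
  db = arma::sum(dOut, 1);
  if (need_dx) {
    mat D = W.t() * dOut;
    col2im(D, g, dX, input.n_rows);
  }
}

// Forward + loss + full backward for one sample.
// wce_variant: 0 = foreground-only (gamma-weighted),
//              1 = balanced (inverse-frequency weights 1/(2 gamma) on
//                  foreground, 1/(2 (1-gamma)) on background).
// wce_mean: divide the cross-entropy term (and its gradient) by the voxel
// count so sigma weighs it against the bounded Dice term.
// [[Rcpp::export]]
List net_fwdbwd_cpp(List weights, NumericVector x, NumericVector gvec,
                    IntegerVector dims, double sigma, double clip, int wce_variant,
                    bool wce_mean) {
  Grid g; g.n1 = dims[0]; g.n2 = dims[1]; g.n3 = dims[2];
  const R_xlen_t N = g.n();
  Cache C;
  forward(weights, vec(x.begin(), x.size()), g, C);

  vec gv(gvec.begin(), N);
  rowvec p = C.p.row(0);
  double gamma = arma::accu(gv) / (double)N;
  double sum_g = arma::accu(gv);
  double sum_p = arma::accu(p);
  double sum_pg = arma::dot(p, gv.t());

  double w_fg = gamma, w_bg = 0.0;
  if (wce_variant == 1) {
    w_fg = (gamma > 0.0) ? 1.0 / (2.0 * gamma) : 0.0;
    w_bg = (gamma < 1.0) ? 1.0 / (2.0 * (1.0 - gamma)) : 0.0;
  }
  double wce = 0.0;
  rowvec dLdp(N, arma::fill::zeros);
  for (R_xlen_t i = 0; i < N; i++) {
    double pi = p(i);
    double pc = std::max(pi, clip);
    double qc = std::max(1.0 - pi, clip);
    if (gv(i) > 0.5) {
      wce += -w_fg * std::log(pc);
      if (pi > clip) dLdp(i) += -w_fg / pc;
    } else if (w_bg > 0.0) {
      wce += -w_bg * std::log(qc);
      if (1.0 - pi > clip) dLdp(i) += w_bg / qc;
    }
  }
  if (wce_mean) {
    wce /= (double)N;
    dLdp /= (double)N;
  }
  double S = sum_p + sum_g + 1.0;
  double A2 = 2.0 * sum_pg + 1.0;
  double dice = 1.0 - A2 / S;
  // dD/dp_i = -(2 g_i S - A2) / S^2
  for (R_xlen_t i = 0; i < N; i++)
    dLdp(i) = sigma * dLdp(i) - (2.0 * gv(i) * S - A2) / (S * S);

  // softmax backward: dz_fg = dL/dp * p(1-p), dz_bg = -dz_fg
  mat dz(2, N);
  for (R_xlen_t i = 0; i < N; i++) {
    double t = dLdp(i) * p(i) * (1.0 - p(i));
    dz(1, i) = t;
    dz(0, i) = -t;
  }

  mat w_in = weights["w_in"], w_r1a = weights["w_r1a"], w_r1b = weights["w_r1b"],
      w_d = weights["w_d"], w_r2a = weights["w_r2a"], w_r2b = weights["w_r2b"],
      w_up = weights["w_up"], w_r3a = weights["w_r3a"], w_r3b = weights["w_r3b"],
      w_head = weights["w_head"];

  mat dW_head, dW_r3b, dW_r3a, dW_up, dW_r2b, dW_r2a, dW_d, dW_r1b, dW_r1a, dW_in;
  vec db_head, db_r3b, db_r3a, db_up, db_r2b, db_r2a, db_d, db_r1b, db_r1a, db_in;
  mat tmp;

  mat dr3;
  conv_bwd(w_head, C.r3, g, dz, dW_head, db_head, dr3, true);
  mat dpre3 = dr3 % arma::conv_to<mat>::from(C.r3 > 0);
  mat ds = dpre3;  // skip branch of the residual add
  mat dh3a;
  conv_bwd(w_r3b, C.h3a, g, dpre3, dW_r3b, db_r3b, dh3a, true);
  mat dpre3a = dh3a % arma::conv_to<mat>::from(C.h3a > 0);
  conv_bwd(w_r3a, C.s, g, dpre3a, dW_r3a, db_r3a, tmp, true);
  ds += tmp;

  mat du = ds;           // s = u + r1
  mat dr1 = ds;
  mat dpre_u = du % arma::conv_to<mat>::from(C.u > 0);
  mat dus;
  conv_bwd(w_up, C.us, g, dpre_u, dW_up, db_up, dus, true);
  mat dr2 = pool_sum(dus, g, C.h);

  mat dpre2 = dr2 % arma::conv_to<mat>::from(C.r2 > 0);
  mat da_d = dpre2;
  mat dh2a;
  conv_bwd(w_r2b, C.h2a, C.h, dpre2, dW_r2b, db_r2b, dh2a, true);
  mat dpre2a = dh2a % arma::conv_to<mat>::from(C.h2a > 0);
  conv_bwd(w_r2a, C.a_d, C.h, dpre2a, dW_r2a, db_r2a, tmp, true);
  da_d += tmp;

  mat dpre_d = da_d % arma::conv_to<mat>::from(C.a_d > 0);
  mat dpd;
  conv_bwd(w_d, C.pd, C.h, dpre_d, dW_d, db_d, dpd, true);
  dr1 += unpool_spread(dpd, C.h, g, 1.0 / 8.0);

  mat dpre1 = dr1 % arma::conv_to<mat>::from(C.r1 > 0);
  mat da_in = dpre1;
  mat dh1a;
  conv_bwd(w_r1b, C.h1a, g, dpre1, dW_r1b, db_r1b, dh1a, true);
  mat dpre1a = dh1a % arma::conv_to<mat>::from(C.h1a > 0);
  conv_bwd(w_r1a, C.a_in, g, dpre1a, dW_r1a, db_r1a, tmp, true);
  da_in += tmp;

  mat dpre_in = da_in % arma::conv_to<mat>::from(C.a_in > 0);
  conv_bwd(w_in, C.x0, g, dpre_in, dW_in, db_in, tmp, false);

  List grads = List::create(
    Named("w_in") = dW_in, Named("b_in") = db_in,
    Named("w_r1a") = dW_r1a, Named("b_r1a") = db_r1a,
    Named("w_r1b") = dW_r1b, Named("b_r1b") = db_r1b,
    Named("w_d") = dW_d, Named("b_d") = db_d,
    Named("w_r2a") = dW_r2a, Named("b_r2a") = db_r2a,
    Named("w_r2b") = dW_r2b, Named("b_r2b") = db_r2b,
    Named("w_up") = dW_up, Named("b_up") = db_up,
    Named("w_r3a") = dW_r3a, Named("b_r3a") = db_r3a,
    Named("w_r3b") = dW_r3b, Named("b_r3b") = db_r3b,
    Named("w_head") = dW_head, Named("b_head") = db_head);
  return List::create(Named("loss") = sigma * wce + dice,
                      Named("wce") = wce, Named("dice") = dice,
                      Named("grads") = grads);
}
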