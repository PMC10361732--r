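// Column-major im2col / col2im kernels for the convolutional layers.
// Activations are (n, S, T, C) arrays; the column matrix is
// (n * S_out * T_out) x (kS * kT * C) with column order (i, j, c).

#include <Rcpp.h>
#include <cstring>
#include <memory>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix pt_im2col(NumericVector X, int n, int S, int T, int C,
                        int kS, int kT, int sS, int sT,
                        int So, int To, int padS, int padT) {
  const R_xlen_t nr = (R_xlen_t)n * So * To;
  NumericMatrix cols(nr, (R_xlen_t)kS * kT * C);
  const double* x = X.begin();
  double* cl = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kT; ++j) {
      for (int i = 0; i < kS; ++i) {
        double* dstcol = cl + ((R_xlen_t)(c * kT + j) * kS + i) * nr;
        for (int to = 0; to < To; ++to) {
          int t_in = to * sT + j - padT;
          if (t_in < 0 || t_in >= T) continue;
          for (int so = 0; so < So; ++so) {
            int s_in = so * sS + i - padS;
            if (s_in < 0 || s_in >= S) continue;
            const double* src = x + (((R_xlen_t)c * T + t_in) * S + s_in) * n;
            double* dst = dstcol + ((R_xlen_t)to * So + so) * n;
            std::memcpy(dst, src, sizeof(double) * n);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector pt_col2im(NumericMatrix dcols, int n, int S, int T, int C,
                        int kS, int kT, int sS, int sT,
                        int So, int To, int padS, int padT) {
  const R_xlen_t nr = (R_xlen_t)n * So * To;
  NumericVector dX((R_xlen_t)n * S * T * C);
  double* dx = dX.begin();
  const double* cl = dcols.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kT; ++j) {
      for (int i = 0; i < kS; ++i) {
        const double* srccol = cl + ((R_xlen_t)(c * kT + j) * kS + i) * nr;
        for (int to = 0; to < To; ++to) {
          int t_in = to * sT + j - padT;
          if (t_in < 0 || t_in >= T) continue;
          for (int so = 0; so < So; ++so) {
            int s_in = so * sS + i - padS;
            if (s_in < 0 || s_in >= S) continue;
            double* dst = dx + (((R_xlen_t)c * T + t_in) * S + s_in) * n;
            const double* src = srccol + ((R_xlen_t)to * So + so) * n;
            for (int b = 0; b < n; ++b) dst[b] += src[b];
          }
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(n, S, T, C);
  return dX;
}

// Fused layer-norm + ReLU. Z is the conv output viewed as an n x M matrix
// (column-major, M = blk * F, filter-major blocks of size blk); gain and
// bias are per filter.

// [[Rcpp::export]]
List pt_ln_relu_fwd(NumericVector Z, int n, int blk, int F,
                    NumericVector gain, NumericVector bias) {
  const R_xlen_t M = (R_xlen_t)blk * F;
  NumericVector A(no_init((R_xlen_t)n * M)), zh(no_init((R_xlen_t)n * M)),
      inv_sd(no_init(n));
  std::vector<double> mu(n, 0.0), ss(n, 0.0);
  const double* z = Z.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* col = z + m * n;
    for (int i = 0; i < n; ++i) mu[i] += col[i];
  }
  for (int i = 0; i < n; ++i) mu[i] /= (double)M;
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* col = z + m * n;
    for (int i = 0; i < n; ++i) {
      double d = col[i] - mu[i];
      ss[i] += d * d;
    }
  }
  for (int i = 0; i < n; ++i) inv_sd[i] = 1.0 / std::sqrt(ss[i] / M + 1e-5);
  double* zhp = zh.begin();
  double* ap = A.begin();
  for (int f = 0; f < F; ++f) {
    const double g = gain[f], b = bias[f];
    for (R_xlen_t m = (R_xlen_t)f * blk; m < (R_xlen_t)(f + 1) * blk; ++m) {
      const double* col = z + m * n;
      double* zc = zhp + m * n;
      double* ac = ap + m * n;
      for (int i = 0; i < n; ++i) {
        double v = (col[i] - mu[i]) * inv_sd[i];
        zc[i] = v;
        double pre = g * v + b;
        ac[i] = pre > 0 ? pre : 0.0;
      }
    }
  }
  return List::create(_["A"] = A, _["zh"] = zh, _["inv_sd"] = inv_sd);
}

// [[Rcpp::export]]
List pt_ln_relu_bwd(NumericVector dA, NumericVector A, NumericVector zh,
                    NumericVector inv_sd, int n, int blk, int F,
                    NumericVector gain) {
  const R_xlen_t M = (R_xlen_t)blk * F;
  NumericVector dZ(no_init((R_xlen_t)n * M)), dgain(F), dbias(F);
  std::unique_ptr<double[]> dzh_buf(new double[(size_t)n * M]);
  double* dzh = dzh_buf.get();
  std::vector<double> m1(n, 0.0), m2(n, 0.0);
  const double* da = dA.begin();
  const double* ap = A.begin();
  const double* zp = zh.begin();
  for (int f = 0; f < F; ++f) {
    const double g = gain[f];
    double dg = 0.0, db = 0.0;
    for (R_xlen_t m = (R_xlen_t)f * blk; m < (R_xlen_t)(f + 1) * blk; ++m) {
      const double* dc = da + m * n;
      const double* ac = ap + m * n;
      const double* zc = zp + m * n;
      double* dzc = dzh + (size_t)m * n;
      for (int i = 0; i < n; ++i) {
        double dpre = ac[i] > 0 ? dc[i] : 0.0;
        dg += dpre * zc[i];
        db += dpre;
        double v = g * dpre;
        dzc[i] = v;
        m1[i] += v;
        m2[i] += v * zc[i];
      }
    }
    dgain[f] = dg;
    dbias[f] = db;
  }
  for (int i = 0; i < n; ++i) { m1[i] /= (double)M; m2[i] /= (double)M; }
  double* out = dZ.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* zc = zp + m * n;
    const double* dzc = dzh + (size_t)m * n;
    double* oc = out + m * n;
    for (int i = 0; i < n; ++i)
      oc[i] = (dzc[i] - m1[i] - zc[i] * m2[i]) * inv_sd[i];
  }
  return List::create(_["dZ"] = dZ, _["dgain"] = dgain, _["dbias"] = dbias);
}
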