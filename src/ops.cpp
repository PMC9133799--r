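// Hot numerical kernels: stride-1 "same"/valid convolution (forward and
// backward) and the space-feature locally-connected readout, operating on
// column-major [H, W, C, N] arrays. Gathers are recomputed in the backward
// pass instead of cached, which keeps training memory flat.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// gather im2col columns of one sample into X [k*k*C, Ho*Wo]
// rows ordered (ky, kx, c) with ky fastest; cols ordered (io fastest)
static void gather_cols(const double* x, int H, int W, int C, int k,
                        int pad, arma::mat& X) {
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int p = io + Ho * jo;
      double* col = X.colptr(p);
      int r = 0;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)c * H * W;
        for (int kx = 0; kx < k; ++kx) {
          const int col_in = jo + kx - pad;
          const bool cok = col_in >= 0 && col_in < W;
          for (int ky = 0; ky < k; ++ky, ++r) {
            const int row_in = io + ky - pad;
            col[r] = (cok && row_in >= 0 && row_in < H)
                         ? xc[row_in + (size_t)col_in * H]
                         : 0.0;
          }
        }
      }
    }
  }
}

// scatter-add the column gradients back onto the (unpadded) input
static void scatter_cols(double* dx, int H, int W, int C, int k, int pad,
                         const arma::mat& dX) {
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int p = io + Ho * jo;
      const double* col = dX.colptr(p);
      int r = 0;
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (size_t)c * H * W;
        for (int kx = 0; kx < k; ++kx) {
          const int col_in = jo + kx - pad;
          const bool cok = col_in >= 0 && col_in < W;
          for (int ky = 0; ky < k; ++ky, ++r) {
            const int row_in = io + ky - pad;
            if (cok && row_in >= 0 && row_in < H) {
              xc[row_in + (size_t)col_in * H] += col[r];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, IntegerVector xdim,
                          NumericMatrix Wm, NumericVector b, int k,
                          int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  const int P = Ho * Wo;
  const int kkC = k * k * C;
  const int F = Wm.ncol();
  arma::mat Wma(Wm.begin(), kkC, F, false);
  arma::rowvec bv(b.begin(), F);
  NumericVector out(Ho * Wo * F * (size_t)N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  arma::mat X(kkC, P);
  for (int n = 0; n < N; ++n) {
    gather_cols(x.begin() + (size_t)n * H * W * C, H, W, C, k, pad, X);
    arma::mat o = X.t() * Wma;            // [P, F]
    o.each_row() += bv;
    std::copy(o.begin(), o.end(), out.begin() + (size_t)n * P * F);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, IntegerVector xdim, NumericMatrix Wm,
                 NumericVector dout, int k, int pad, bool need_dx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  const int P = Ho * Wo;
  const int kkC = k * k * C;
  const int F = Wm.ncol();
  arma::mat Wma(Wm.begin(), kkC, F, false);
  arma::mat dW(kkC, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector(x.size());
    dx.attr("dim") = xdim;
  }
  arma::mat X(kkC, P);
  for (int n = 0; n < N; ++n) {
    gather_cols(x.begin() + (size_t)n * H * W * C, H, W, C, k, pad, X);
    // dout slice is [Ho, Wo, F] column-major -> [P, F] matrix view
    arma::mat dmat(const_cast<double*>(dout.begin()) + (size_t)n * P * F,
                   P, F, false);
    dW += X * dmat;
    db += arma::sum(dmat, 0);
    if (need_dx) {
      arma::mat dX = Wma * dmat.t();      // [kkC, P]
      scatter_cols(dx.begin() + (size_t)n * H * W * C, H, W, C, k, pad,
                   dX);
    }
  }
  return List::create(_["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()),
                      _["dx"] = dx);
}

// space-feature locally-connected readout: per sample, stack the 3x3
// neighbourhood (valid, trim 1), pool with per-voxel spatial maps, weight
// channels per voxel. z: [g, g, C, N]; Wsp: [P, Nv]; Wch: [9C, Nv].
// [[Rcpp::export]]
NumericMatrix cpp_readout_fw(NumericVector z, IntegerVector zdim,
                             NumericMatrix Wsp, NumericMatrix Wch) {
  const int g = zdim[0], C = zdim[2], N = zdim[3];
  const int k = 3, pad = 0;
  const int go = g - 2;
  const int P = go * go;
  const int kkC = k * k * C;
  const int Nv = Wsp.ncol();
  arma::mat Wspa(Wsp.begin(), P, Nv, false);
  arma::mat Wcha(Wch.begin(), kkC, Nv, false);
  NumericMatrix outs(Nv, N);
  arma::mat X(kkC, P);
  for (int n = 0; n < N; ++n) {
    gather_cols(z.begin() + (size_t)n * g * g * C, g, g, C, k, pad, X);
    arma::mat M = X * Wspa;               // [kkC, Nv]
    arma::rowvec o = arma::sum(M % Wcha, 0);
    std::copy(o.begin(), o.end(), outs.begin() + (size_t)n * Nv);
  }
  return outs;
}

// backward of the readout; doutb: [Nv, N] upstream gradient of this
// branch's per-voxel outputs. Returns dWsp, dWch and dz.
// [[Rcpp::export]]
List cpp_readout_bw(NumericVector z, IntegerVector zdim,
                    NumericMatrix Wsp, NumericMatrix Wch,
                    NumericMatrix doutb) {
  const int g = zdim[0], C = zdim[2], N = zdim[3];
  const int k = 3, pad = 0;
  const int go = g - 2;
  const int P = go * go;
  const int kkC = k * k * C;
  const int Nv = Wsp.ncol();
  arma::mat Wspa(Wsp.begin(), P, Nv, false);
  arma::mat Wcha(Wch.begin(), kkC, Nv, false);
  arma::mat dWsp(P, Nv, arma::fill::zeros);
  arma::mat dWch(kkC, Nv, arma::fill::zeros);
  NumericVector dz(z.size());
  dz.attr("dim") = zdim;
  arma::mat X(kkC, P);
  for (int n = 0; n < N; ++n) {
    gather_cols(z.begin() + (size_t)n * g * g * C, g, g, C, k, pad, X);
    arma::mat M = X * Wspa;               // [kkC, Nv]
    arma::rowvec dv(const_cast<double*>(doutb.begin()) + (size_t)n * Nv,
                    Nv, false);
    dWch += M.each_row() % dv;
    arma::mat dM = Wcha.each_row() % dv;  // [kkC, Nv]
    dWsp += X.t() * dM;
    arma::mat dX = dM * Wspa.t();         // [kkC, P]
    scatter_cols(dz.begin() + (size_t)n * g * g * C, g, g, C, k, pad,
                 dX);
  }
  return List::create(_["dWsp"] = wrap(dWsp), _["dWch"] = wrap(dWch),
                      _["dz"] = dz);
}

// ---- batch normalization over (H, W, N) per channel ----------------------

// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W, chw = hw * C;
  NumericVector mu(C), va(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + n * chw + c * hw;
      for (size_t i = 0; i < hw; ++i) {
        s += p[i];
        s2 += p[i] * p[i];
      }
    }
    const double m = s / (hw * N);
    mu[c] = m;
    va[c] = s2 / (hw * N) - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// [[Rcpp::export]]
NumericVector cpp_bn_apply(NumericVector x, IntegerVector xdim,
                           NumericVector gamma, NumericVector beta,
                           NumericVector mu, NumericVector inv) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W, chw = hw * C;
  NumericVector y(x.size());
  y.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + n * chw + c * hw;
      double* q = y.begin() + n * chw + c * hw;
      const double a = gamma[c] * inv[c];
      const double bsh = beta[c] - a * mu[c];
      for (size_t i = 0; i < hw; ++i) q[i] = a * p[i] + bsh;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, IntegerVector xdim, NumericVector dout,
               NumericVector gamma, NumericVector mu, NumericVector inv,
               bool training) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W, chw = hw * C;
  const double m = (double)hw * N;
  NumericVector dgamma(C), dbeta(C);
  NumericVector dx(x.size());
  dx.attr("dim") = xdim;
  for (int c = 0; c < C; ++c) {
    double sd_ = 0.0, sdx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + n * chw + c * hw;
      const double* d = dout.begin() + n * chw + c * hw;
      for (size_t i = 0; i < hw; ++i) {
        sd_ += d[i];
        sdx += d[i] * (p[i] - mu[c]) * inv[c];
      }
    }
    dgamma[c] = sdx;
    dbeta[c] = sd_;
    const double gi = gamma[c] * inv[c];
    const double md = sd_ / m, mdx = sdx / m;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + n * chw + c * hw;
      const double* d = dout.begin() + n * chw + c * hw;
      double* o = dx.begin() + n * chw + c * hw;
      if (training) {
        for (size_t i = 0; i < hw; ++i) {
          o[i] = gi * (d[i] - md - (p[i] - mu[c]) * inv[c] * mdx);
        }
      } else {
        for (size_t i = 0; i < hw; ++i) o[i] = gi * d[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---- x2 average pooling --------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_pool2_fw(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const size_t hw = (size_t)H * W, ohw = (size_t)Ho * Wo;
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* p = x.begin() + s * hw;
    double* q = y.begin() + s * ohw;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double* b = p + 2 * i + (size_t)2 * j * H;
        q[i + (size_t)j * Ho] =
            0.25 * (b[0] + b[1] + b[H] + b[H + 1]);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_pool2_bw(NumericVector dout, IntegerVector odim) {
  const int Ho = odim[0], Wo = odim[1], C = odim[2], N = odim[3];
  const int H = Ho * 2, W = Wo * 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t hw = (size_t)H * W, ohw = (size_t)Ho * Wo;
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* q = dout.begin() + s * ohw;
    double* p = dx.begin() + s * hw;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double g = 0.25 * q[i + (size_t)j * Ho];
        double* b = p + 2 * i + (size_t)2 * j * H;
        b[0] = g;
        b[1] = g;
        b[H] = g;
        b[H + 1] = g;
      }
    }
  }
  return dx;
}
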