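// 3D convolution forward/backward via im2col + GEMM.
// Feature maps are stored channel-first, column-major: an array with
// dim = (C, T, H, W), so index = c + C*(t + T*(h + H*w)).
// Weights are a (C_out x C_in*kt*kh*kw) matrix whose row layout matches the
// im2col row order k = c + C*(dt + kt*(dh + kh*dw)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static void im2col(const double* x, int C, int T, int H, int W,
                   int kt, int kh, int kw, int st, int sh, int sw,
                   int pt, int ph, int pw, int To, int Ho, int Wo,
                   arma::mat& cols) {
  const int K = C * kt * kh * kw;
  cols.zeros(K, (arma::uword)To * Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int to = 0; to < To; ++to) {
        arma::uword l = to + (arma::uword)To * (ho + (arma::uword)Ho * wo);
        double* col = cols.colptr(l);
        for (int dw = 0; dw < kw; ++dw) {
          int wi = wo * sw - pw + dw;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            int hi = ho * sh - ph + dh;
            if (hi < 0 || hi >= H) continue;
            for (int dt = 0; dt < kt; ++dt) {
              int ti = to * st - pt + dt;
              if (ti < 0 || ti >= T) continue;
              const double* xp = x + (size_t)C * (ti + (size_t)T * (hi + (size_t)H * wi));
              double* cp = col + (size_t)C * (dt + (size_t)kt * (dh + (size_t)kh * dw));
              for (int c = 0; c < C; ++c) cp[c] = xp[c];
            }
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int C, int T, int H, int W,
                   int kt, int kh, int kw, int st, int sh, int sw,
                   int pt, int ph, int pw, int To, int Ho, int Wo,
                   double* dx) {
  std::fill(dx, dx + (size_t)C * T * H * W, 0.0);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int to = 0; to < To; ++to) {
        arma::uword l = to + (arma::uword)To * (ho + (arma::uword)Ho * wo);
        const double* col = cols.colptr(l);
        for (int dw = 0; dw < kw; ++dw) {
          int wi = wo * sw - pw + dw;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            int hi = ho * sh - ph + dh;
            if (hi < 0 || hi >= H) continue;
            for (int dt = 0; dt < kt; ++dt) {
              int ti = to * st - pt + dt;
              if (ti < 0 || ti >= T) continue;
              double* xp = dx + (size_t)C * (ti + (size_t)T * (hi + (size_t)H * wi));
              const double* cp = col + (size_t)C * (dt + (size_t)kt * (dh + (size_t)kh * dw));
              for (int c = 0; c < C; ++c) xp[c] += cp[c];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv3d_forward(NumericVector x, IntegerVector xdim,
                        NumericMatrix w, NumericVector b,
                        IntegerVector kdim, IntegerVector stride,
                        IntegerVector pad) {
  const int C = xdim[0], T = xdim[1], H = xdim[2], W = xdim[3];
  const int kt = kdim[0], kh = kdim[1], kw = kdim[2];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_size(T, kt, st, pt), Ho = out_size(H, kh, sh, ph),
            Wo = out_size(W, kw, sw, pw);
  if (To < 1 || Ho < 1 || Wo < 1)
    stop("conv3d: output would be empty (input %dx%dx%d, kernel %dx%dx%d)",
         T, H, W, kt, kh, kw);
  const int Co = w.nrow();
  if (w.ncol() != C * kt * kh * kw)
    stop("conv3d: weight has %d columns, expected %d", w.ncol(), C * kt * kh * kw);
  arma::mat cols;
  im2col(x.begin(), C, T, H, W, kt, kh, kw, st, sh, sw, pt, ph, pw,
         To, Ho, Wo, cols);
  arma::mat wm(const_cast<double*>(w.begin()), Co, w.ncol(), false, true);
  arma::mat out = wm * cols;
  out.each_col() += arma::vec(const_cast<double*>(b.begin()), Co, false, true);
  NumericVector y(out.begin(), out.end());
  y.attr("dim") = IntegerVector::create(Co, To, Ho, Wo);
  return List::create(_["y"] = y,
                      _["ydim"] = IntegerVector::create(Co, To, Ho, Wo));
}

// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, IntegerVector xdim,
                         NumericMatrix w, NumericVector dy,
                         IntegerVector ydim, IntegerVector kdim,
                         IntegerVector stride, IntegerVector pad) {
  const int C = xdim[0], T = xdim[1], H = xdim[2], W = xdim[3];
  const int kt = kdim[0], kh = kdim[1], kw = kdim[2];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int Co = ydim[0], To = ydim[1], Ho = ydim[2], Wo = ydim[3];
  arma::mat cols;
  im2col(x.begin(), C, T, H, W, kt, kh, kw, st, sh, sw, pt, ph, pw,
         To, Ho, Wo, cols);
  arma::mat wm(const_cast<double*>(w.begin()), Co, w.ncol(), false, true);
  arma::mat dym(const_cast<double*>(dy.begin()), Co,
                (arma::uword)To * Ho * Wo, false, true);
  arma::mat dw = dym * cols.t();
  arma::vec db = arma::sum(dym, 1);
  arma::mat dcols = wm.t() * dym;
  NumericVector dx((size_t)C * T * H * W);
  col2im(dcols, C, T, H, W, kt, kh, kw, st, sh, sw, pt, ph, pw, To, Ho, Wo,
         dx.begin());
  dx.attr("dim") = IntegerVector::create(C, T, H, W);
  NumericMatrix dwR(Co, w.ncol());
  std::copy(dw.begin(), dw.end(), dwR.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwR,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
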