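// Convolution kernels for the network engine.
//
// Tensor layout follows R column-major arrays: activations are
// (H, W, C, N) and weights are (kh, kw, Cin, Cout).  Padding is applied
// on the R side; these kernels assume "valid" convolution with stride s.
//
// im2col row ordering matches the R flattening of the weight array
// (kh fastest, then kw, then channel), so the GEMM reduces to a single
// reshape on each side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int s, int Ho, int Wo, arma::mat& cols) {
  // cols: (kh*kw*C) x (Ho*Wo); fill one output column at a time so writes
  // are contiguous and reads run down image columns
  const size_t nr = cols.n_rows;
  double* cp = cols.memptr();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* out = cp + (size_t)(wo * Ho + ho) * nr;
      const int h0 = ho * s, w0 = wo * s;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + ((size_t)c * W + w0) * H + h0;
        for (int j = 0; j < kw; ++j) {
          const double* src = xc + (size_t)j * H;
          for (int i = 0; i < kh; ++i) {
            out[i + kh * (j + kw * c)] = src[i];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& cols, double* dx, int H, int W, int C,
                       int kh, int kw, int s, int Ho, int Wo) {
  const size_t nr = cols.n_rows;
  const double* cp = cols.memptr();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* src = cp + (size_t)(wo * Ho + ho) * nr;
      const int h0 = ho * s, w0 = wo * s;
      for (int c = 0; c < C; ++c) {
        double* xc = dx + ((size_t)c * W + w0) * H + h0;
        for (int j = 0; j < kw; ++j) {
          double* dst = xc + (size_t)j * H;
          for (int i = 0; i < kh; ++i) {
            dst[i] += src[i + kh * (j + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], K = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and kernel");
  int Ho = (H - kh) / stride + 1;
  int Wo = (W - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than input");

  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, K, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), K, false, true);

  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * K * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, K, N);

  arma::mat cols(kh * kw * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, Ho, Wo, cols);
    // Ymat: (Ho*Wo) x K, column-major matches (Ho,Wo,K) flattening
    arma::mat Ym(y.begin() + (size_t)n * Ho * Wo * K, Ho * Wo, K, false, true);
    Ym = cols.t() * Wm;
    Ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, bool compute_dx = true,
                         bool compute_dw = true) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], K = wd[3];
  int Ho = (H - kh) / stride + 1;
  int Wo = (W - kw) / stride + 1;

  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, K, false, true);

  NumericVector dx;
  if (compute_dx) {
    dx = NumericVector(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
    std::fill(dx.begin(), dx.end(), 0.0);
    dx.attr("dim") = xd;
  }
  arma::mat dW(kh * kw * C, K, arma::fill::zeros);
  arma::rowvec db(K, arma::fill::zeros);

  arma::mat cols(kh * kw * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    arma::mat Dm(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * K,
                 Ho * Wo, K, false, true);
    if (compute_dw) {
      im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, Ho,
             Wo, cols);
      dW += cols * Dm;
      db += arma::sum(Dm, 0);
    }
    if (compute_dx) {
      arma::mat dcols = Wm * Dm.t();
      col2im_add(dcols, dx.begin() + (size_t)n * H * W * C, H, W, C, kh, kw,
                 stride, Ho, Wo);
    }
  }

  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
NumericVector cpp_scatter_add(IntegerVector idx, NumericVector val, int n) {
  NumericVector out(n);
  const int m = idx.size();
  for (int i = 0; i < m; ++i) out[idx[i] - 1] += val[i];
  return out;
}
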