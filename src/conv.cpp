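// Batched 2-D convolution kernels (im2col + GEMM) used by the segmentation
// backbone. Tensors are R arrays in column-major [H, W, C, N] layout; filters
// are [K, K, Cin, Cout] with K odd and "same" zero padding.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Fill the im2col matrix: rows index (ho, wo, n), cols index (kh, kw, ci).
static void im2col(const double *x, int H, int W, int Cin, int N, int K,
                   int stride, int Ho, int Wo, arma::mat &M) {
  const int pad = (K - 1) / 2;
  for (int n = 0; n < N; ++n)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < K; ++kw)
        for (int kh = 0; kh < K; ++kh) {
          const int col = kh + K * (kw + K * ci);
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride + kw - pad;
            const int rbase = Ho * (wo + Wo * n);
            if (w < 0 || w >= W) {
              for (int ho = 0; ho < Ho; ++ho) M(rbase + ho, col) = 0.0;
              continue;
            }
            const double *xcol = x + H * (w + W * (ci + Cin * n));
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride + kh - pad;
              M(rbase + ho, col) = (h >= 0 && h < H) ? xcol[h] : 0.0;
            }
          }
        }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericVector w, NumericVector b,
                          int stride) {
  int xd[4], wd[4];
  dims4(x, xd); dims4(w, wd);
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  if (wd[1] != K || wd[2] != Cin) stop("filter dims do not match input");
  const int pad = (K - 1) / 2;
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;

  arma::mat M(Ho * Wo * N, K * K * Cin);
  im2col(REAL(x), H, W, Cin, N, K, stride, Ho, Wo, M);
  const arma::mat Wm(const_cast<double *>(REAL(w)), K * K * Cin, Cout, false);
  arma::mat Y = M * Wm;
  Y.each_row() += arma::rowvec(const_cast<double *>(REAL(b)), Cout, false);

  NumericVector y(Ho * Wo * Cout * N);
  double *yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          yp[ho + Ho * (wo + Wo * (co + Cout * n))] =
              Y(ho + Ho * (wo + Wo * n), co);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, NumericVector w, NumericVector dy,
                 int stride) {
  int xd[4], wd[4], yd[4];
  dims4(x, xd); dims4(w, wd); dims4(dy, yd);
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int pad = (K - 1) / 2;

  arma::mat M(Ho * Wo * N, K * K * Cin);
  im2col(REAL(x), H, W, Cin, N, K, stride, Ho, Wo, M);

  arma::mat dY(Ho * Wo * N, Cout);
  const double *dyp = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          dY(ho + Ho * (wo + Wo * n), co) =
              dyp[ho + Ho * (wo + Wo * (co + Cout * n))];

  const arma::mat Wm(const_cast<double *>(REAL(w)), K * K * Cin, Cout, false);
  arma::mat dWm = M.t() * dY;
  arma::rowvec dbv = arma::sum(dY, 0);
  arma::mat dM = dY * Wm.t();

  NumericVector dx(H * W * Cin * N);
  double *dxp = REAL(dx);
  for (int n = 0; n < N; ++n)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < K; ++kw)
        for (int kh = 0; kh < K; ++kh) {
          const int col = kh + K * (kw + K * ci);
          for (int wo = 0; wo < Wo; ++wo) {
            const int w2 = wo * stride + kw - pad;
            if (w2 < 0 || w2 >= W) continue;
            double *dxcol = dxp + H * (w2 + W * (ci + Cin * n));
            const int rbase = Ho * (wo + Wo * n);
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride + kh - pad;
              if (h >= 0 && h < H) dxcol[h] += dM(rbase + ho, col);
            }
          }
        }
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);

  NumericVector dw(dWm.begin(), dWm.end());
  dw.attr("dim") = IntegerVector::create(K, K, Cin, Cout);
  NumericVector db(dbv.begin(), dbv.end());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
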