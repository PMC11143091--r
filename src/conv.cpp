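#include <Rcpp.h>
using namespace Rcpp;

// Row-wise 1D cross-correlation primitives used by the compact CNN.
// Series are stored as *columns* of X (time runs down a column), so the
// innermost loops walk contiguous memory.

// Valid cross-correlation of every column of X (T x R) with every kernel in
// W (K x F): Y[t, r, f] = sum_k X[t + k - 1, r] * W[k, f].
// Caller handles padding; T_out = T - K + 1.
// [[Rcpp::export]]
NumericVector conv_cols_fwd(NumericMatrix X, NumericMatrix W) {
  const int T = X.nrow(), R = X.ncol(), K = W.nrow(), F = W.ncol();
  const int To = T - K + 1;
  if (To < 1) stop("kernel longer than (padded) series");
  NumericVector Y(static_cast<R_xlen_t>(To) * R * F);
  Y.attr("dim") = IntegerVector::create(To, R, F);
  double* y = Y.begin();
  const double* x = X.begin();
  const double* w = W.begin();
  for (int f = 0; f < F; ++f) {
    const double* wf = w + static_cast<R_xlen_t>(f) * K;
    for (int r = 0; r < R; ++r) {
      const double* xr = x + static_cast<R_xlen_t>(r) * T;
      double* yr = y + (static_cast<R_xlen_t>(f) * R + r) * To;
      for (int t = 0; t < To; ++t) {
        const double* xt = xr + t;
        // four accumulators break the FP dependency chain (the compiler
        // cannot reorder a single running sum)
        double a0 = 0, a1 = 0, a2 = 0, a3 = 0;
        int k = 0;
        for (; k + 3 < K; k += 4) {
          a0 += xt[k] * wf[k];
          a1 += xt[k + 1] * wf[k + 1];
          a2 += xt[k + 2] * wf[k + 2];
          a3 += xt[k + 3] * wf[k + 3];
        }
        for (; k < K; ++k) a0 += xt[k] * wf[k];
        yr[t] = (a0 + a1) + (a2 + a3);
      }
    }
  }
  return Y;
}

// Gradient w.r.t. the (padded) input of conv_cols_fwd.
// dX[s, r] = sum_f sum_k dY[s - k + 1, r, f] * W[k, f]  (valid indices only).
// [[Rcpp::export]]
NumericMatrix conv_cols_dx(NumericVector dY, NumericMatrix W, int T) {
  IntegerVector d = dY.attr("dim");
  const int To = d[0], R = d[1], F = d[2];
  const int K = W.nrow();
  if (W.ncol() != F) stop("kernel bank/f gradient mismatch");
  if (To != T - K + 1) stop("dimension mismatch in conv_cols_dx");
  NumericMatrix dX(T, R);
  double* dx = dX.begin();
  const double* dy = dY.begin();
  const double* w = W.begin();
  for (int f = 0; f < F; ++f) {
    const double* wf = w + static_cast<R_xlen_t>(f) * K;
    for (int r = 0; r < R; ++r) {
      const double* dyr = dy + (static_cast<R_xlen_t>(f) * R + r) * To;
      double* dxr = dx + static_cast<R_xlen_t>(r) * T;
      for (int t = 0; t < To; ++t) {
        const double g = dyr[t];
        if (g != 0.0) {
          double* dxt = dxr + t;
          for (int k = 0; k < K; ++k) dxt[k] += g * wf[k];
        }
      }
    }
  }
  return dX;
}

// Gradient w.r.t. the kernels: dW[k, f] = sum_r sum_t dY[t, r, f] * X[t+k-1, r].
// [[Rcpp::export]]
NumericMatrix conv_cols_dw(NumericMatrix X, NumericVector dY, int K) {
  IntegerVector d = dY.attr("dim");
  const int To = d[0], R = d[1], F = d[2];
  const int T = X.nrow();
  if (X.ncol() != R || To != T - K + 1) stop("dimension mismatch in conv_cols_dw");
  NumericMatrix dW(K, F);
  double* dw = dW.begin();
  const double* x = X.begin();
  const double* dy = dY.begin();
  for (int f = 0; f < F; ++f) {
    double* dwf = dw + static_cast<R_xlen_t>(f) * K;
    for (int r = 0; r < R; ++r) {
      const double* xr = x + static_cast<R_xlen_t>(r) * T;
      const double* dyr = dy + (static_cast<R_xlen_t>(f) * R + r) * To;
      for (int t = 0; t < To; ++t) {
        const double g = dyr[t];
        if (g != 0.0) {
          const double* xt = xr + t;
          for (int k = 0; k < K; ++k) dwf[k] += g * xt[k];
        }
      }
    }
  }
  return dW;
}

// im2col companion to the GEMM formulation of the temporal convolution:
// P[(r * To) + t, k] = X[t + k, r]; then Y = P %*% W, dW = t(P) %*% dY.
// [[Rcpp::export]]
NumericMatrix im2col_cols(NumericMatrix X, int K) {
  const int T = X.nrow(), R = X.ncol();
  const int To = T - K + 1;
  if (To < 1) stop("kernel longer than (padded) series");
  NumericMatrix P(static_cast<R_xlen_t>(To) * R, K);
  const double* x = X.begin(); double* p = P.begin();
  const R_xlen_t nr = static_cast<R_xlen_t>(To) * R;
  for (int k = 0; k < K; ++k) {
    double* pc = p + static_cast<R_xlen_t>(k) * nr;
    for (int r = 0; r < R; ++r) {
      const double* xc = x + static_cast<R_xlen_t>(r) * T + k;
      double* pr = pc + static_cast<R_xlen_t>(r) * To;
      std::copy(xc, xc + To, pr);
    }
  }
  return P;
}

// scatter-add inverse of im2col for the input gradient:
// dX[t + k, r] += Q[(r * To) + t, k]
// [[Rcpp::export]]
NumericMatrix col2im_cols(NumericMatrix Q, int T) {
  const int K = Q.ncol();
  const int To = T - K + 1;
  const int R = Q.nrow() / To;
  NumericMatrix dX(T, R);
  const double* q = Q.begin(); double* dx = dX.begin();
  const R_xlen_t nr = Q.nrow();
  for (int k = 0; k < K; ++k) {
    const double* qc = q + static_cast<R_xlen_t>(k) * nr;
    for (int r = 0; r < R; ++r) {
      const double* qr = qc + static_cast<R_xlen_t>(r) * To;
      double* xc = dx + static_cast<R_xlen_t>(r) * T + k;
      for (int t = 0; t < To; ++t) xc[t] += qr[t];
    }
  }
  return dX;
}
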