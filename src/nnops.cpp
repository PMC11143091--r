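#include <Rcpp.h>
using namespace Rcpp;

// Single-pass elementwise / per-column kernels for the network's batch-norm,
// activation and depthwise stages (the profiler showed sweep()/aperm() copies
// dominating the training step).

// [[Rcpp::export]]
NumericVector elu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  for (R_xlen_t i = 0; i < y.size(); ++i)
    if (y[i] < 0) y[i] = std::expm1(y[i]);
  return y;
}

// dy * elu'(z) expressed through the forward output y = elu(z)
// [[Rcpp::export]]
NumericVector elu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dz(dy.size());
  dz.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dz[i] = y[i] >= 0 ? dy[i] : dy[i] * (y[i] + 1.0);
  return dz;
}

// y[i, j] = x[i, j] * a[j] + b[j]  (x is N x M, column-major)
// [[Rcpp::export]]
NumericVector col_affine(NumericVector x, NumericVector a, NumericVector b,
                         int M) {
  const R_xlen_t N = x.size() / M;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* px = x.begin(); double* py = y.begin();
  for (int j = 0; j < M; ++j) {
    const double aj = a[j], bj = b[j];
    const double* xc = px + static_cast<R_xlen_t>(j) * N;
    double* yc = py + static_cast<R_xlen_t>(j) * N;
    for (R_xlen_t i = 0; i < N; ++i) yc[i] = xc[i] * aj + bj;
  }
  return y;
}

// per-column mean and variance (biased) in one pass
// [[Rcpp::export]]
List col_moments(NumericVector x, int M) {
  const R_xlen_t N = x.size() / M;
  NumericVector mu(M), va(M);
  const double* px = x.begin();
  for (int j = 0; j < M; ++j) {
    const double* xc = px + static_cast<R_xlen_t>(j) * N;
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < N; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    mu[j] = s / N;
    va[j] = s2 / N - mu[j] * mu[j];
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// xhat[i,j] = (x[i,j] - mu[j]) * istd[j]
// [[Rcpp::export]]
NumericVector col_standardize(NumericVector x, NumericVector mu,
                              NumericVector istd, int M) {
  const R_xlen_t N = x.size() / M;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* px = x.begin(); double* py = y.begin();
  for (int j = 0; j < M; ++j) {
    const double m = mu[j], s = istd[j];
    const double* xc = px + static_cast<R_xlen_t>(j) * N;
    double* yc = py + static_cast<R_xlen_t>(j) * N;
    for (R_xlen_t i = 0; i < N; ++i) yc[i] = (xc[i] - m) * s;
  }
  return y;
}

// batch-norm backward reduction: per column j,
//   s1[j] = mean_i(dy[i,j]) * g[j],  s2[j] = mean_i(dy[i,j] * xhat[i,j]) * g[j]
//   also dgamma[j] = sum_i(dy * xhat), dbeta[j] = sum_i(dy)
// [[Rcpp::export]]
List bn_bwd_sums(NumericVector dy, NumericVector xhat, int M) {
  const R_xlen_t N = dy.size() / M;
  NumericVector s1(M), s2(M), dg(M), db(M);
  const double* pd = dy.begin(); const double* ph = xhat.begin();
  for (int j = 0; j < M; ++j) {
    const double* dc = pd + static_cast<R_xlen_t>(j) * N;
    const double* hc = ph + static_cast<R_xlen_t>(j) * N;
    double a = 0, b = 0;
    for (R_xlen_t i = 0; i < N; ++i) { a += dc[i]; b += dc[i] * hc[i]; }
    db[j] = a; dg[j] = b;
    s1[j] = a / N; s2[j] = b / N;
  }
  return List::create(_["s1"] = s1, _["s2"] = s2,
                      _["dgamma"] = dg, _["dbeta"] = db);
}

// train-mode batch-norm input gradient, single pass:
//   dx[i,j] = g[j] * istd[j] * (dy[i,j] - s1[j] - xhat[i,j] * s2[j])
// [[Rcpp::export]]
NumericVector bn_bwd_dx(NumericVector dy, NumericVector xhat,
                        NumericVector s1, NumericVector s2,
                        NumericVector gistd, int M) {
  const R_xlen_t N = dy.size() / M;
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* pd = dy.begin(); const double* ph = xhat.begin();
  double* px = dx.begin();
  for (int j = 0; j < M; ++j) {
    const double a = s1[j], b = s2[j], g = gistd[j];
    const double* dc = pd + static_cast<R_xlen_t>(j) * N;
    const double* hc = ph + static_cast<R_xlen_t>(j) * N;
    double* xc = px + static_cast<R_xlen_t>(j) * N;
    for (R_xlen_t i = 0; i < N; ++i) xc[i] = g * (dc[i] - a - hc[i] * b);
  }
  return dx;
}

// Depthwise spatial stage operating directly on the temporal-conv layout
// Y (T x C*n x F1, column index (c, i) with c fastest):
//   Z[t, i, m] = sum_c Wd[c, m] * Y[t, (i-1)C + c, f1(m)],  m = (f1-1)D + d.
// [[Rcpp::export]]
NumericVector depthwise_fwd(NumericVector Y, NumericMatrix Wd, int D) {
  IntegerVector dy = Y.attr("dim");
  const int T = dy[0], Cn = dy[1], F1 = dy[2];
  const int C = Wd.nrow(), F2 = Wd.ncol();
  const int n = Cn / C;
  NumericVector Z(static_cast<R_xlen_t>(T) * n * F2);
  Z.attr("dim") = IntegerVector::create(T, n, F2);
  const double* py = Y.begin(); double* pz = Z.begin();
  for (int m = 0; m < F2; ++m) {
    const int f1 = m / D;
    for (int i = 0; i < n; ++i) {
      double* zc = pz + (static_cast<R_xlen_t>(m) * n + i) * T;
      for (int c = 0; c < C; ++c) {
        const double w = Wd(c, m);
        const double* yc = py + (static_cast<R_xlen_t>(f1) * Cn + i * C + c) * T;
        for (int t = 0; t < T; ++t) zc[t] += w * yc[t];
      }
    }
  }
  return Z;
}

// gradient w.r.t. Y of depthwise_fwd
// [[Rcpp::export]]
NumericVector depthwise_dx(NumericVector dZ, NumericMatrix Wd, int F1) {
  IntegerVector dd = dZ.attr("dim");
  const int T = dd[0], n = dd[1], F2 = dd[2];
  const int C = Wd.nrow();
  const int D = F2 / F1;
  NumericVector dY(static_cast<R_xlen_t>(T) * C * n * F1);
  dY.attr("dim") = IntegerVector::create(T, C * n, F1);
  const double* pz = dZ.begin(); double* py = dY.begin();
  for (int m = 0; m < F2; ++m) {
    const int f1 = m / D;
    for (int i = 0; i < n; ++i) {
      const double* zc = pz + (static_cast<R_xlen_t>(m) * n + i) * T;
      for (int c = 0; c < C; ++c) {
        const double w = Wd(c, m);
        double* yc = py + (static_cast<R_xlen_t>(f1) * C * n + i * C + c) * T;
        for (int t = 0; t < T; ++t) yc[t] += w * zc[t];
      }
    }
  }
  return dY;
}

// gradient w.r.t. Wd of depthwise_fwd
// [[Rcpp::export]]
NumericMatrix depthwise_dw(NumericVector Y, NumericVector dZ, int C, int D) {
  IntegerVector dd = dZ.attr("dim");
  const int T = dd[0], n = dd[1], F2 = dd[2];
  NumericMatrix dW(C, F2);
  const double* py = Y.begin(); const double* pz = dZ.begin();
  for (int m = 0; m < F2; ++m) {
    const int f1 = m / D;
    for (int i = 0; i < n; ++i) {
      const double* zc = pz + (static_cast<R_xlen_t>(m) * n + i) * T;
      for (int c = 0; c < C; ++c) {
        const double* yc = py + (static_cast<R_xlen_t>(f1) * C * n + i * C + c) * T;
        double acc = 0;
        for (int t = 0; t < T; ++t) acc += yc[t] * zc[t];
        dW(c, m) += acc;
      }
    }
  }
  return dW;
}
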