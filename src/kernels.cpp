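// Fused conv -> ReLU -> max-pool forward and backward kernels for the
// 1-D sequence CNN. Tensors are base-R arrays in (N, L, C) column-major
// layout (sample index fastest). Fusing the three layer steps keeps the
// working set per pooling window in L1 cache and never materialises the
// full convolution map: since ReLU is monotone, max(relu(z)) = relu(max(z)),
// so pooling is done on the raw convolution scores and the rectifier is
// applied to the pooled maximum. The backward pass routes gradient only
// through each window's argmax, and only where the pooled activation is
// positive (otherwise every window element was <= 0 and the rectifier
// blocks the gradient).

#include <Rcpp.h>
using namespace Rcpp;

static inline NumericVector alloc_num(R_xlen_t n) {
  return NumericVector(Rcpp::no_init(n));
}
static inline IntegerVector alloc_int(R_xlen_t n) {
  return IntegerVector(Rcpp::no_init(n));
}

// X: (N, L, C), W: (k, C, F), b: length F, pool width pw, stride ps.
// Returns out: (N, Lq, F) pooled rectified activations and arg: (N, Lq, F)
// 1-based convolution position of each window maximum.
// Lq = (L - k + 1 - pw) / ps + 1.
// [[Rcpp::export(name = ".cpp_convpool_fw")]]
List cpp_convpool_fw(NumericVector X, NumericVector W, NumericVector b,
                     int pw, int ps) {
  IntegerVector dX = X.attr("dim"), dW = W.attr("dim");
  const int N = dX[0], L = dX[1], C = dX[2];
  const int k = dW[0], F = dW[2];
  const int Lo = L - k + 1;
  const int Lq = (Lo - pw) / ps + 1;
  NumericVector O = alloc_num((R_xlen_t)N * Lq * F);
  IntegerVector arg = alloc_int((R_xlen_t)N * Lq * F);
  double* o = REAL(O);
  int* g = INTEGER(arg);
  const double* x = REAL(X);
  const double* w = REAL(W);
  std::vector<double> zbuf(N);
  for (int q = 0; q < Lq; ++q) {
    const int p0 = q * ps;
    for (int f = 0; f < F; ++f) {
      double* os = o + ((R_xlen_t)f * Lq + q) * N;
      int* gs = g + ((R_xlen_t)f * Lq + q) * N;
      const double* wf = w + (R_xlen_t)f * k * C;
      for (int jj = 0; jj < pw; ++jj) {
        const int p = p0 + jj;
        double* zb = zbuf.data();
        const double bf = b[f];
        for (int n = 0; n < N; ++n) zb[n] = bf;
        for (int c = 0; c < C; ++c) {
          const double* xc = x + ((R_xlen_t)c * L + p) * N;
          const double* wfc = wf + (R_xlen_t)c * k;
          for (int j = 0; j < k; ++j) {
            const double wv = wfc[j];
            if (wv == 0.0) continue;
            const double* xs = xc + (R_xlen_t)j * N;
            for (int n = 0; n < N; ++n) zb[n] += wv * xs[n];
          }
        }
        if (jj == 0) {
          for (int n = 0; n < N; ++n) { os[n] = zb[n]; gs[n] = p + 1; }
        } else {
          for (int n = 0; n < N; ++n) {
            if (zb[n] > os[n]) { os[n] = zb[n]; gs[n] = p + 1; }
          }
        }
      }
      for (int n = 0; n < N; ++n) if (os[n] < 0.0) os[n] = 0.0;
    }
  }
  O.attr("dim") = IntegerVector::create(N, Lq, F);
  arg.attr("dim") = IntegerVector::create(N, Lq, F);
  return List::create(Named("out") = O, Named("arg") = arg);
}

// Backward of the fused block. dO: (N, Lq, F) gradient on the pooled
// activations; out/arg from the forward pass; X and W as in the forward.
// Returns dW (k, C, F), db (F) and, when need_dx, dX (N, L, C).
// [[Rcpp::export(name = ".cpp_convpool_bw")]]
List cpp_convpool_bw(NumericVector dO, NumericVector O, IntegerVector arg,
                     NumericVector X, NumericVector W, bool need_dx) {
  IntegerVector dd = dO.attr("dim"), dXd = X.attr("dim"),
    dWd = W.attr("dim");
  const int N = dXd[0], L = dXd[1], C = dXd[2];
  const int k = dWd[0], F = dWd[2];
  const int Lq = dd[1];
  NumericVector dW((R_xlen_t)k * C * F), db(F);
  const double* dop = REAL(dO);
  const double* op = REAL(O);
  const int* g = INTEGER(arg);
  const double* x = REAL(X);
  const double* w = REAL(W);
  double* dwp = REAL(dW);
  double* dbp = REAL(db);
  NumericVector dXv;
  double* dxp = 0;
  if (need_dx) {
    dXv = NumericVector((R_xlen_t)N * L * C);
    dxp = REAL(dXv);
  }
  for (int f = 0; f < F; ++f) {
    const double* dof = dop + (R_xlen_t)f * N * Lq;
    const double* of = op + (R_xlen_t)f * N * Lq;
    const int* gf = g + (R_xlen_t)f * N * Lq;
    double* dwf = dwp + (R_xlen_t)f * k * C;
    const double* wf = w + (R_xlen_t)f * k * C;
    double acc_b = 0.0;
    for (int q = 0; q < Lq; ++q) {
      const double* ds = dof + (R_xlen_t)q * N;
      const double* os = of + (R_xlen_t)q * N;
      const int* gs = gf + (R_xlen_t)q * N;
      for (int n = 0; n < N; ++n) {
        if (os[n] <= 0.0) continue;        // rectifier blocked the window
        const double gr = ds[n];
        if (gr == 0.0) continue;
        const int p = gs[n] - 1;           // conv position of the maximum
        acc_b += gr;
        for (int c = 0; c < C; ++c) {
          const double* xc = x + ((R_xlen_t)c * L + p) * N + n;
          double* dwfc = dwf + (R_xlen_t)c * k;
          for (int j = 0; j < k; ++j)
            dwfc[j] += xc[(R_xlen_t)j * N] * gr;
        }
        if (need_dx) {
          for (int c = 0; c < C; ++c) {
            double* dxc = dxp + ((R_xlen_t)c * L + p) * N + n;
            const double* wfc = wf + (R_xlen_t)c * k;
            for (int j = 0; j < k; ++j)
              dxc[(R_xlen_t)j * N] += wfc[j] * gr;
          }
        }
      }
    }
    dbp[f] = acc_b;
  }
  dW.attr("dim") = IntegerVector::create(k, C, F);
  List out = List::create(Named("dW") = dW, Named("db") = db,
                          Named("dX") = R_NilValue);
  if (need_dx) {
    dXv.attr("dim") = IntegerVector::create(N, L, C);
    out["dX"] = dXv;
  }
  return out;
}
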