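#include <Rcpp.h>
using namespace Rcpp;

// Theta-method time stepper for a tridiagonal spatial operator L,
//   vol_i dC_i/dt = (L C)_i,   i = 2..N (row 1 is Dirichlet: C_1 = g(t)).
// The system matrix A = vol/dt - theta*L is constant in time, so the Thomas
// elimination coefficients are computed once and each step is O(N).
//
// Ll[i], Ld[i], Lu[i] are the coefficients of C[i-1], C[i], C[i+1] in row i
// (0-based; Ll[0] and Lu[N-1] are ignored). g holds the Dirichlet value at
// every stored time, length nt+1. Returns the N x (nt+1) solution matrix.
// [[Rcpp::export]]
NumericMatrix theta_step_tridiag(NumericVector vol,
                                 NumericVector Ll,
                                 NumericVector Ld,
                                 NumericVector Lu,
                                 NumericVector g,
                                 double dt,
                                 double theta) {
  const int N = vol.size();
  const int nt = g.size() - 1;
  NumericMatrix C(N, nt + 1);

  std::vector<double> Al(N), Ad(N), Au(N), cp(N), denom(N), rhs(N), work(N);
  Ad[0] = 1.0; Au[0] = 0.0; Al[0] = 0.0;
  for (int i = 1; i < N; ++i) {
    Al[i] = -theta * Ll[i];
    Ad[i] = vol[i] / dt - theta * Ld[i];
    Au[i] = (i < N - 1) ? -theta * Lu[i] : 0.0;
  }
  denom[0] = Ad[0];
  cp[0] = Au[0] / denom[0];
  for (int i = 1; i < N; ++i) {
    denom[i] = Ad[i] - Al[i] * cp[i - 1];
    cp[i] = Au[i] / denom[i];
  }

  for (int i = 0; i < N; ++i) C(i, 0) = 0.0;
  C(0, 0) = g[0];

  const double omt = 1.0 - theta;
  for (int n = 0; n < nt; ++n) {
    rhs[0] = g[n + 1];
    for (int i = 1; i < N; ++i) {
      double lc = Ll[i] * C(i - 1, n) + Ld[i] * C(i, n);
      if (i < N - 1) lc += Lu[i] * C(i + 1, n);
      rhs[i] = vol[i] / dt * C(i, n) + omt * lc;
    }
    work[0] = rhs[0] / denom[0];
    for (int i = 1; i < N; ++i)
      work[i] = (rhs[i] - Al[i] * work[i - 1]) / denom[i];
    C(N - 1, n + 1) = work[N - 1];
    for (int i = N - 2; i >= 0; --i)
      C(i, n + 1) = work[i] - cp[i] * C(i + 1, n + 1);
  }
  return C;
}
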