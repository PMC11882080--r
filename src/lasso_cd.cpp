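#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-descent lasso over many right-hand sides sharing one Gram matrix.
//
// Solves, for each column n of B, min_s 1/2 ||x_n - D s||^2 + lambda ||s||_1
// given G = D'D (M x M) and B = D'X (M x N). Only inner products enter the
// coordinate updates, so the patch matrix itself is never touched here.
// S0 supplies a warm start (pass a zero matrix for a cold start); warm starts
// make the full-data objective monotone across alternating-minimisation epochs.
// [[Rcpp::export]]
NumericMatrix lasso_cd_encode(NumericMatrix G, NumericMatrix B,
                              double lambda, double tol, int maxIter,
                              NumericMatrix S0) {
  const int M = G.nrow(), N = B.ncol();
  if (G.ncol() != M) stop("G must be square");
  if (B.nrow() != M) stop("nrow(B) must equal nrow(G)");
  if (S0.nrow() != M || S0.ncol() != N) stop("S0 has wrong dimensions");

  NumericMatrix S(M, N);
  std::vector<double> s(M), Gs(M);

  for (int n = 0; n < N; ++n) {
    // initialise from warm start and cache Gs = G s
    for (int k = 0; k < M; ++k) s[k] = S0(k, n);
    for (int k = 0; k < M; ++k) {
      double acc = 0.0;
      for (int j = 0; j < M; ++j) acc += G(k, j) * s[j];
      Gs[k] = acc;
    }
    for (int it = 0; it < maxIter; ++it) {
      double maxDelta = 0.0;
      for (int k = 0; k < M; ++k) {
        const double gkk = G(k, k);
        if (gkk <= 0.0) { continue; }  // degenerate atom: leave coefficient
        const double r = B(k, n) - Gs[k] + gkk * s[k];
        double snew;
        if (r > lambda)       snew = (r - lambda) / gkk;
        else if (r < -lambda) snew = (r + lambda) / gkk;
        else                  snew = 0.0;       // ties at zero broken toward zero
        const double d = snew - s[k];
        if (d != 0.0) {
          for (int j = 0; j < M; ++j) Gs[j] += d * G(j, k);
          s[k] = snew;
          const double ad = std::fabs(d);
          if (ad > maxDelta) maxDelta = ad;
        }
      }
      if (maxDelta < tol) break;
    }
    for (int k = 0; k < M; ++k) S(k, n) = s[k];
  }
  return S;
}
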