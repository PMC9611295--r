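#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Phase lag index matrix for one window.
// phase: samples x channels matrix of instantaneous phases in (-pi, pi]
// (channels in columns so the time loop is cache-contiguous).
// PLI(i,j) = | mean_t sign( wrap(phase_i(t) - phase_j(t)) ) |, with the
// difference wrapped to (-pi, pi] and sign(0) contributing 0.
// [[Rcpp::export]]
NumericMatrix pli_matrix_cpp(NumericMatrix phase) {
  const int nt = phase.nrow();
  const int n = phase.ncol();
  const double PI = 3.14159265358979323846;
  NumericMatrix out(n, n);
  for (int i = 0; i < n - 1; ++i) {
    const double* pi_col = &phase(0, i);
    for (int j = i + 1; j < n; ++j) {
      const double* pj_col = &phase(0, j);
      double acc = 0.0;
      for (int t = 0; t < nt; ++t) {
        double d = pi_col[t] - pj_col[t];
        if (d > PI) d -= 2.0 * PI;
        else if (d <= -PI) d += 2.0 * PI;
        if (d > 0.0) acc += 1.0;
        else if (d < 0.0) acc -= 1.0;
      }
      double v = std::fabs(acc / nt);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}

// Kernel-RFE removal scores for an RBF SVM, all features at once.
// sv: support vectors (rows) x features; a: per-SV coefficients
// alpha_i * y_i. Score_j = (W2 - W2_(-j)) / 2 with
// W2 = sum_ab a_a a_b K(x_a, x_b) and K recomputed without feature j,
// coefficients held fixed. The score is signed: in the linear limit it
// reduces to w_j^2 / 2 >= 0, while for RBF kernels a noise feature whose
// removal inflates within-kernel similarity scores negative and is
// eliminated first.
// [[Rcpp::export]]
NumericVector rfe_scores_cpp(NumericMatrix sv, NumericVector a,
                             double gamma) {
  const int s = sv.nrow();
  const int p = sv.ncol();
  NumericVector scores(p);
  // pairwise squared distances and weighted kernel M_ab = a_a a_b K_ab
  std::vector<double> M(s * s, 0.0);
  double w2 = 0.0;
  for (int b = 0; b < s; ++b) {
    for (int c = 0; c < s; ++c) {
      double d2 = 0.0;
      for (int f = 0; f < p; ++f) {
        double d = sv(b, f) - sv(c, f);
        d2 += d * d;
      }
      double m = a[b] * a[c] * std::exp(-gamma * d2);
      M[b * s + c] = m;
      w2 += m;
    }
  }
  for (int f = 0; f < p; ++f) {
    double w2m = 0.0;
    for (int b = 0; b < s; ++b) {
      const double xf = sv(b, f);
      for (int c = 0; c < s; ++c) {
        double d = xf - sv(c, f);
        w2m += M[b * s + c] * std::exp(gamma * d * d);
      }
    }
    scores[f] = (w2 - w2m) / 2.0;
  }
  return scores;
}
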