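#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-matching entropies. Distances between embedded vectors are
// Chebyshev (max of coordinate-wise absolute differences).

// Approximate entropy: N-m+1 templates of length m, self-matches included,
// denominator N-m+1; ApEn = Phi^m(r) - Phi^{m+1}(r) with
// Phi^m = mean_i log C_i^m(r).
static double phi_m(const NumericVector& u, int m, double r) {
  const int N = u.size();
  const int n = N - m + 1;  // number of templates
  std::vector<int> counts(n, 0);
  for (int i = 0; i < n; ++i) {
    counts[i]++;  // self-match
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(u[i + k] - u[j + k]);
        if (a > d) d = a;
        if (d > r) break;
      }
      if (d <= r) { counts[i]++; counts[j]++; }
    }
  }
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::log((double)counts[i] / n);
  return s / n;
}

// [[Rcpp::export(name = ".apenC")]]
double apenC(NumericVector u, int m, double r) {
  const int N = u.size();
  if (N < m + 2) stop("series too short for ApEn at m=%d", m);
  if (r <= 0.0) return 0.0;  // constant series convention
  return phi_m(u, m, r) - phi_m(u, m + 1, r);
}

// Sample entropy: templates i = 1..N-m for both lengths, self-matches
// excluded; SampEn = -log(A/B) with A (length m+1) and B (length m) match
// counts over unordered pairs. B == 0 or A == 0 => +Inf (degenerate flag).
// [[Rcpp::export(name = ".sampenC")]]
double sampenC(NumericVector u, int m, double r) {
  const int N = u.size();
  if (N < m + 2) stop("series too short for SampEn at m=%d", m);
  if (r <= 0.0) {
    // constant series: every pair matches at both lengths => A == B => 0
    bool constant = true;
    for (int i = 1; i < N; ++i) if (u[i] != u[0]) { constant = false; break; }
    if (constant) return 0.0;
    return R_PosInf;
  }
  const int n = N - m;  // templates so that both m and m+1 vectors exist
  long long A = 0, B = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(u[i + k] - u[j + k]);
        if (a > d) d = a;
        if (d > r) break;
      }
      if (d <= r) {
        B++;
        double a = std::fabs(u[i + m] - u[j + m]);
        if (a <= r && d <= r) A++;
      }
    }
  }
  if (B == 0 || A == 0) return R_PosInf;
  return -std::log((double)A / (double)B);
}
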