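// Approximate entropy kernel (Pincus formulation, Chebyshev distance,
// self-matches included).  Template counting is exact: the pair loop
// exploits symmetry d(i,j) = d(j,i) and derives the (m+1)-length matches
// from the m-length matches in the same pass, so the integer counts -- and
// hence the result -- are identical to a naive double loop.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  const int L = x.size();
  if (L <= m + 1) stop("series too short for embedding length m");
  for (int i = 0; i < L; ++i)
    if (!R_finite(x[i])) stop("non-finite samples in input series");
  if (r < 0) stop("tolerance r must be non-negative");
  if (r == 0) return 0.0;  // degenerate tolerance: treated as fully regular

  const double* p = x.begin();
  const int nt1 = L - m + 1;  // templates of length m
  const int nt2 = L - m;      // templates of length m + 1
  std::vector<int> cnt1(nt1, 1), cnt2(nt2, 1);  // self-matches included

  for (int i = 0; i < nt1; ++i) {
    for (int j = i + 1; j < nt1; ++j) {
      bool match = true;
      for (int u = 0; u < m; ++u) {
        if (std::fabs(p[i + u] - p[j + u]) > r) { match = false; break; }
      }
      if (!match) continue;
      ++cnt1[i]; ++cnt1[j];
      if (j < nt2 && std::fabs(p[i + m] - p[j + m]) <= r) {
        ++cnt2[i]; ++cnt2[j];
      }
    }
  }
  double phi1 = 0.0, phi2 = 0.0;
  for (int i = 0; i < nt1; ++i)
    phi1 += std::log(static_cast<double>(cnt1[i]) / nt1);
  phi1 /= nt1;
  for (int i = 0; i < nt2; ++i)
    phi2 += std::log(static_cast<double>(cnt2[i]) / nt2);
  phi2 /= nt2;
  return phi1 - phi2;
}
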