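#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Circular binary segmentation scan.
//
// For cut points 0 <= i < j <= n (arc = x[i+1..j], 1-based; width k = j - i,
// 1 <= k <= n-1):
//   T(i,j) = |mean(arc) - mean(complement)| / sqrt(1/k + 1/(n-k))
// The data SD is permutation-invariant, so it is omitted from the statistic;
// the permutation test calibrates the null distribution.
//
// For fixed width k the statistic is monotone in the arc sum A = S[i+k]-S[i]:
//   T = |A*c1 - c2| * w,  c1 = 1/k + 1/(n-k),  c2 = total/(n-k),  w = 1/sqrt(c1)
// so per width only the extreme arc sums matter. That keeps the inner loop to
// two comparisons per cell.

static void partial_sums(const std::vector<double>& x,
                         std::vector<double>& S) {
  const int n = (int)x.size();
  S.resize(n + 1);
  S[0] = 0.0;
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
}

// Exhaustive maximum with argmax.
static void max_arc(const std::vector<double>& S, int n,
                    double& best, int& bi, int& bj) {
  const double total = S[n];
  best = -1.0; bi = 0; bj = 1;
  for (int k = 1; k < n; ++k) {
    const double c1 = 1.0 / k + 1.0 / (double)(n - k);
    const double c2 = total / (double)(n - k);
    const double w = 1.0 / std::sqrt(c1);
    double amax = S[k] - S[0], amin = amax;
    int imax = 0, imin = 0;
    for (int i = 1; i + k <= n; ++i) {
      const double a = S[i + k] - S[i];
      if (a > amax) { amax = a; imax = i; }
      if (a < amin) { amin = a; imin = i; }
    }
    const double thi = std::fabs(amax * c1 - c2) * w;
    const double tlo = std::fabs(amin * c1 - c2) * w;
    if (thi > best) { best = thi; bi = imax; bj = imax + k; }
    if (tlo > best) { best = tlo; bi = imin; bj = imin + k; }
  }
}

// Early-exit check: does any arc exceed `thresh`?
static bool max_arc_exceeds(const std::vector<double>& S, int n,
                            double thresh) {
  const double total = S[n];
  for (int k = 1; k < n; ++k) {
    const double c1 = 1.0 / k + 1.0 / (double)(n - k);
    const double c2 = total / (double)(n - k);
    const double b = thresh * std::sqrt(c1);      // |A*c1 - c2| must beat b
    const double hi = (b + c2) / c1;
    const double lo = (c2 - b) / c1;
    for (int i = 0; i + k <= n; ++i) {
      const double a = S[i + k] - S[i];
      if (a > hi || a < lo) return true;
    }
  }
  return false;
}

// [[Rcpp::export(name = ".cpp_max_arc")]]
List cpp_max_arc(NumericVector x) {
  const int n = x.size();
  if (n < 2) return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = n);
  std::vector<double> v(x.begin(), x.end()), S;
  partial_sums(v, S);
  double best; int bi, bj;
  max_arc(S, n, best, bi, bj);
  return List::create(_["stat"] = best, _["i"] = bi, _["j"] = bj);
}

// Permutation test for the best arc of one segment, with sequential early
// stopping in both directions: stop "not significant" once the exceedance
// count makes p < alpha impossible at full nperm, and stop "significant"
// once (exc + 1) / (m + 1) < alpha with m >= min_perm permutations done.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".cpp_cbs_split")]]
List cpp_cbs_split(NumericVector x, int nperm, double alpha, int min_perm) {
  const int n = x.size();
  if (n < 4) {
    return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = n,
                        _["p"] = 1.0, _["signif"] = false, _["nperm"] = 0);
  }
  std::vector<double> v(x.begin(), x.end()), S;
  partial_sums(v, S);
  double obs; int bi, bj;
  max_arc(S, n, obs, bi, bj);
  if (obs <= 0.0) {   // constant segment
    return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj,
                        _["p"] = 1.0, _["signif"] = false, _["nperm"] = 0);
  }

  const int exc_stop = (int)std::floor(alpha * nperm) + 1;
  int exc = 0, m = 0;
  std::vector<double> perm(v);
  RNGScope scope;
  for (m = 1; m <= nperm; ++m) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    partial_sums(perm, S);
    if (max_arc_exceeds(S, n, obs)) ++exc;
    if (exc >= exc_stop) break;                    // cannot reach p < alpha
    if (m >= min_perm && (exc + 1.0) / (m + 1.0) < alpha) break;
  }
  if (m > nperm) m = nperm;
  const double p = (exc + 1.0) / (m + 1.0);
  return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj,
                      _["p"] = p, _["signif"] = (p < alpha),
                      _["nperm"] = m);
}
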