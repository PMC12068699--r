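#include <Rcpp.h>
using namespace Rcpp;

// Symmetric beta-binomial machinery.
//
// All log-gamma decompositions below are grouped so that swapping a and
// (n - a) produces a bit-identical result: lgamma(a+1) + lgamma(n-a+1) and
// lgamma(a+alpha) + lgamma(n-a+alpha) are plain commutative sums, and the
// terms that depend only on n are computed once. This makes every
// likelihood in the package exactly invariant under relabelling which
// allele is called "A", which is a contract of the model (the A allele is
// an arbitrary label).

static inline double lg(double x) { return R::lgammafn(x); }

// log C(n, a), symmetric in a <-> n - a at the bit level
// [[Rcpp::export(name = ".lchooseSym")]]
NumericVector lchoose_sym(IntegerVector a, IntegerVector n) {
  R_xlen_t m = a.size();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i)
    out[i] = lg(n[i] + 1.0) - (lg(a[i] + 1.0) + lg(n[i] - a[i] + 1.0));
  return out;
}

// [[Rcpp::export(name = ".sbbLogPmfCpp")]]
NumericVector sbb_logpmf_cpp(IntegerVector a, IntegerVector n, double alpha) {
  R_xlen_t m = a.size();
  NumericVector out(m);
  double lb0 = 2.0 * lg(alpha) - lg(2.0 * alpha);
  for (R_xlen_t i = 0; i < m; ++i) {
    double lc = lg(n[i] + 1.0) - (lg(a[i] + 1.0) + lg(n[i] - a[i] + 1.0));
    double lb = (lg(a[i] + alpha) + lg(n[i] - a[i] + alpha)) -
      lg(n[i] + 2.0 * alpha);
    out[i] = lc + lb - lb0;
  }
  return out;
}

// Table of lgamma(x + alpha) for x = 0..maxn and lgamma(n + 2 alpha);
// reduces the per-evaluation lgamma count from O(#obs) to O(max N), which
// dominates optimizer runtime in the simulation studies.
struct SbbTab {
  std::vector<double> gx;   // lgamma(x + alpha), x = 0..maxn
  std::vector<double> gn;   // lgamma(n + 2 alpha), n = 0..maxn
  double lb0;               // 2 lgamma(alpha) - lgamma(2 alpha)
  SbbTab(double alpha, int maxn) : gx(maxn + 1), gn(maxn + 1) {
    for (int x = 0; x <= maxn; ++x) {
      gx[x] = lg(x + alpha);
      gn[x] = lg(x + 2.0 * alpha);
    }
    lb0 = 2.0 * lg(alpha) - lg(2.0 * alpha);
  }
  inline double logpmf(int a, int n, double lc) const {
    // (gx[a] + gx[n-a]) grouped first: commutative, so a <-> n-a is
    // bit-identical
    return lc + (gx[a] + gx[n - a]) - gn[n] - lb0;
  }
};

// Sum of single-component symmetric beta-binomial log pmfs.
// lc must hold lchoose_sym(a, n).
// [[Rcpp::export(name = ".sbbLogLikCpp")]]
double sbb_loglik_cpp(IntegerVector a, IntegerVector n, NumericVector lc,
                      double alpha) {
  R_xlen_t m = a.size();
  if (m == 0) return 0.0;
  int maxn = 0;
  for (R_xlen_t i = 0; i < m; ++i) if (n[i] > maxn) maxn = n[i];
  SbbTab t(alpha, maxn);
  double ll = 0.0;
  for (R_xlen_t i = 0; i < m; ++i) ll += t.logpmf(a[i], n[i], lc[i]);
  return ll;
}

// Two-component mixture log-likelihood with group-specific mixing weights.
// grp is 0-based into pis; log-sum-exp keeps the mixture stable when one
// component is astronomically unlikely.
// [[Rcpp::export(name = ".groupedLogLikCpp")]]
double grouped_loglik_cpp(IntegerVector a, IntegerVector n, NumericVector lc,
                          IntegerVector grp, double alpha1, double alpha2,
                          NumericVector pis) {
  R_xlen_t m = a.size();
  if (m == 0) return 0.0;
  int maxn = 0;
  for (R_xlen_t i = 0; i < m; ++i) if (n[i] > maxn) maxn = n[i];
  SbbTab t1(alpha1, maxn), t2(alpha2, maxn);
  double ll = 0.0;
  for (R_xlen_t i = 0; i < m; ++i) {
    double l1 = t1.logpmf(a[i], n[i], lc[i]);
    double l2 = t2.logpmf(a[i], n[i], lc[i]);
    double p = pis[grp[i]];
    if (p >= 1.0) { ll += l1; continue; }
    if (p <= 0.0) { ll += l2; continue; }
    double x1 = std::log(p) + l1;
    double x2 = std::log1p(-p) + l2;
    double hi = x1 > x2 ? x1 : x2;
    double lo = x1 > x2 ? x2 : x1;
    ll += hi + std::log1p(std::exp(lo - hi));
  }
  return ll;
}
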