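#ifndef ASPMINE_FET_H
#define ASPMINE_FET_H

#include <Rcpp.h>
#include <cmath>
#include <algorithm>

// Two-tailed doubled-tail Fisher exact test on the 2x2 table
//   (d_pos, n_pos - d_pos / d_neg, n_neg - d_neg), d_all = d_pos + d_neg.
//
// These functions MUST mirror hypergeom_g()/fet_pvalue() in R/significance.R
// term for term (same R::lchoose calls, same summation order, same tie
// tolerance) so that the pruned C++ calibration and the naive R calibration
// agree bitwise.

inline double fet_g(int n_pos, int n_neg, int d_all, int a) {
  if (a < 0 || a > n_pos || d_all - a < 0 || d_all - a > n_neg) return 0.0;
  return std::exp(R::lchoose((double)n_pos, (double)a)
                  + R::lchoose((double)n_neg, (double)(d_all - a))
                  - R::lchoose((double)(n_pos + n_neg), (double)d_all));
}

inline double fet_p(int n_pos, int n_neg, int d_all, int d_pos) {
  int lo = std::max(0, d_all - n_neg);
  int hi = std::min(n_pos, d_all);
  double gobs = fet_g(n_pos, n_neg, d_all, d_pos);
  double cut = gobs * (1.0 + 1e-7);  // tie tolerance, as in fisher.test
  double s = 0.0;
  for (int a = lo; a <= hi; ++a) {
    double ga = fet_g(n_pos, n_neg, d_all, a);
    if (ga <= cut) s += ga;
  }
  double p = 2.0 * s;
  return p < 1.0 ? p : 1.0;
}

// Label-free lower bound on the FET p-value of a pattern with support d_all
// and of every extension of it (extensions can only lose support, and the
// hypergeometric pmf at the boundary cells is nonincreasing in support).
inline double fet_plow(int n_pos, int n_neg, int d_all) {
  double g1 = fet_g(n_pos, n_neg, std::min(d_all, n_pos), std::min(d_all, n_pos));
  double g2 = fet_g(n_pos, n_neg, std::min(d_all, n_neg), 0);
  return g1 < g2 ? g1 : g2;
}

#endif
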