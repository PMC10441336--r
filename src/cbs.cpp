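#include <Rcpp.h>
using namespace Rcpp;

// Max-|t| arc search for circular binary segmentation.
//
// For a vector of n bins, consider arcs (i, j], 0 <= i < j <= n, holding
// m = j - i bins. The two-sample t statistic between the arc and its
// complement is monotone in |mean_arc - mean_rest| * sqrt(m (n - m)),
// since the pooled variance is arc-invariant. Valid arcs keep every
// resulting segment (arc, complement, interior flanks) >= min_width bins.
//
// `stop_at` > 0 allows an early exit as soon as some arc reaches that
// value (used when only exceedance of an observed statistic matters).

static double arc_scan(const double* x, int n, int min_width,
                       const double* w, double stop_at,
                       int* best_i, int* best_j) {
  std::vector<double> S(n + 1);
  S[0] = 0.0;
  for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t];
  double best = -1.0;
  for (int i = 0; i <= n - min_width; ++i) {
    if (i > 0 && i < min_width) continue;
    double Si = S[i];
    for (int j = i + min_width; j <= n; ++j) {
      if (j < n && n - j < min_width) continue;
      int m = j - i;
      if (n - m < min_width) continue;
      double d = (S[j] - Si) / m - (S[n] - S[j] + Si) / (n - m);
      double stat = std::fabs(d) * w[m];
      if (stat > best) {
        best = stat;
        if (best_i) *best_i = i;
        if (best_j) *best_j = j;
        if (stop_at > 0 && best >= stop_at) return best;
      }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".arc_max")]]
List arc_max(NumericVector x, int min_width) {
  int n = x.size();
  std::vector<double> w(n + 1);
  for (int m = 1; m <= n; ++m) w[m] = std::sqrt((double)m * (n - m));
  int bi = -1, bj = -1;
  double stat = arc_scan(x.begin(), n, min_width, w.data(), -1.0, &bi, &bj);
  return List::create(_["stat"] = stat, _["i"] = bi, _["j"] = bj);
}

// Sequential (curtailed) permutation test of an observed arc statistic.
//
// Permutes x with R's RNG (reproducible under set.seed) and counts
// permuted max statistics >= obs. Stops as soon as the decision at level
// `alpha` is settled:
//   return -2  accept: the 99.9% upper confidence bound on p < alpha
//   return -1  reject: exceedances already force p >= alpha, or the
//              99.9% lower confidence bound on p > alpha
// otherwise returns the final exceedance count after n_perm permutations
// (caller computes p = (count + 1) / (n_perm + 1)).
// [[Rcpp::export(name = ".arc_perm_exceed")]]
int arc_perm_exceed(NumericVector x, int min_width, double obs,
                    int n_perm, double alpha) {
  int n = x.size();
  std::vector<double> w(n + 1);
  for (int m = 1; m <= n; ++m) w[m] = std::sqrt((double)m * (n - m));
  std::vector<double> y(x.begin(), x.end());
  int limit = (int)std::ceil(alpha * (n_perm + 1)) - 1;
  int exceed = 0;
  // earliest t at which exceed == e allows acceptance
  int t_accept = -1;
  {
    double t = std::log(0.001) / std::log1p(-alpha);
    t_accept = (int)std::ceil(t);
  }
  for (int p = 1; p <= n_perm; ++p) {
    for (int t = n - 1; t > 0; --t) {   // Fisher-Yates with R RNG
      int k = (int)(unif_rand() * (t + 1));
      if (k > t) k = t;
      std::swap(y[t], y[k]);
    }
    double s = arc_scan(y.data(), n, min_width, w.data(), obs,
                        nullptr, nullptr);
    if (s >= obs) {
      if (++exceed > limit) return -1;
      // recompute acceptance horizon for the new exceedance count
      t_accept = -1;
    }
    if (t_accept < 0) {
      int t = std::max(p, exceed + 1);
      while (t <= n_perm &&
             R::qbeta(0.999, exceed + 1.0, (double)(t - exceed), 1, 0)
               >= alpha)
        ++t;
      t_accept = t;  // may be n_perm + 1: no early acceptance possible
    }
    if (p >= t_accept && t_accept <= n_perm) return -2;
    if (exceed > 0 && p % 64 == 0 &&
        R::qbeta(0.001, (double)exceed, (double)(p - exceed + 1), 1, 0)
          > alpha)
      return -1;
  }
  return exceed;
}
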