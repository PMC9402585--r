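// Hot kernels for the survival-screening core: fuzzy 2-means on a single
// score vector, the two-group log-rank chi-square, and the random-gene-set
// screen that evaluates millions of (gene set, sample subset) pairs.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Type-7 quantile of sorted data.
static double quantile7(const std::vector<double>& xs, double p) {
  const int n = (int)xs.size();
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  int hi = std::min(lo + 1, n - 1);
  return xs[lo] + (h - lo) * (xs[hi] - xs[lo]);
}

// Fuzzy c-means with k = 2 on a vector. Centers start at the 25th/75th
// percentiles (fallback min/max when those coincide), memberships use
// fuzzifier m, samples are hard-assigned to the cluster of maximal
// membership. Returns false when all values are identical (degenerate).
// On success lab[i] is 0 for the low-center cluster, 1 for the high one.
static bool fcm2(const double* x, int n, double m,
                 std::vector<int>& lab, double* centers_out) {
  std::vector<double> xs(x, x + n);
  std::sort(xs.begin(), xs.end());
  if (xs.front() == xs.back()) return false;
  double c1 = quantile7(xs, 0.25), c2 = quantile7(xs, 0.75);
  if (c1 == c2) { c1 = xs.front(); c2 = xs.back(); }

  const double e = 2.0 / (m - 1.0);
  const bool sq = std::fabs(e - 2.0) < 1e-12;  // m == 2 fast path
  std::vector<double> u1(n);
  // Center tolerance 1e-6 suffices: only the hard assignment boundary
  // matters downstream, and it is stable well before the centers settle.
  for (int iter = 0; iter < 50; ++iter) {
    for (int i = 0; i < n; ++i) {
      double d1 = std::fabs(x[i] - c1), d2 = std::fabs(x[i] - c2);
      if (d1 == 0.0 && d2 == 0.0) u1[i] = 0.5;
      else if (d1 == 0.0) u1[i] = 1.0;
      else if (d2 == 0.0) u1[i] = 0.0;
      else if (sq) {
        double a = d1 * d1, b = d2 * d2;
        u1[i] = b / (a + b);
      } else {
        u1[i] = 1.0 / (1.0 + std::pow(d1 / d2, e));
      }
    }
    double n1 = 0, s1 = 0, n2 = 0, s2 = 0;
    for (int i = 0; i < n; ++i) {
      double w1 = sq ? u1[i] * u1[i] : std::pow(u1[i], m);
      double u2 = 1.0 - u1[i];
      double w2 = sq ? u2 * u2 : std::pow(u2, m);
      n1 += w1; s1 += w1 * x[i];
      n2 += w2; s2 += w2 * x[i];
    }
    double c1n = n1 > 0 ? s1 / n1 : c1;
    double c2n = n2 > 0 ? s2 / n2 : c2;
    double delta = std::max(std::fabs(c1n - c1), std::fabs(c2n - c2));
    c1 = c1n; c2 = c2n;
    if (delta < 1e-6) break;
  }
  lab.resize(n);
  // cluster 0 = lower center; membership ties go to it.
  bool flip = c1 > c2;
  for (int i = 0; i < n; ++i) {
    int hi = u1[i] < 0.5 ? 1 : 0;   // 1 means "cluster of c2"
    lab[i] = flip ? 1 - hi : hi;
  }
  centers_out[0] = std::min(c1, c2);
  centers_out[1] = std::max(c1, c2);
  return true;
}

// Two-group log-rank chi-square p-value. time/event must be sorted by
// ascending time; group is 0/1. Returns 1.0 for degenerate inputs (a group
// empty, no events, or zero variance).
static double logrank_p_sorted(const double* time, const int* event,
                               const int* group, int n) {
  int tot1 = 0;
  for (int i = 0; i < n; ++i) tot1 += group[i];
  if (tot1 == 0 || tot1 == n) return 1.0;
  double U = 0.0, V = 0.0;
  int at_risk = n, at_risk1 = tot1;
  int i = 0;
  bool any_event = false;
  while (i < n) {
    int j = i;
    int d = 0, d1 = 0, c1 = 0;
    while (j < n && time[j] == time[i]) {
      d += event[j];
      d1 += event[j] * group[j];
      c1 += group[j];
      ++j;
    }
    if (d > 0) {
      any_event = true;
      double nn = at_risk, n1 = at_risk1;
      U += d1 - d * n1 / nn;
      if (at_risk > 1) {
        V += d * (n1 / nn) * (1.0 - n1 / nn) * (nn - d) / (nn - 1.0);
      }
    }
    at_risk -= (j - i);
    at_risk1 -= c1;
    i = j;
  }
  if (!any_event || V <= 0.0) return 1.0;
  double chisq = U * U / V;
  return R::pchisq(chisq, 1.0, 0, 0);
}

// [[Rcpp::export(name = ".fcm2_cpp")]]
List fcm2_cpp(NumericVector x, double m) {
  std::vector<int> lab;
  double centers[2];
  if (!fcm2(x.begin(), x.size(), m, lab, centers)) {
    return List::create(_["ok"] = false);
  }
  IntegerVector cluster(x.size());
  for (int i = 0; i < x.size(); ++i) cluster[i] = lab[i] + 1;
  return List::create(_["ok"] = true, _["cluster"] = cluster,
                      _["centers"] = NumericVector::create(centers[0], centers[1]));
}

// [[Rcpp::export(name = ".logrank_p_cpp")]]
double logrank_p_cpp(NumericVector time, IntegerVector event,
                     IntegerVector group) {
  int n = time.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a] < time[b]; });
  std::vector<double> t(n);
  std::vector<int> ev(n), gr(n);
  for (int i = 0; i < n; ++i) {
    t[i] = time[ord[i]];
    ev[i] = event[ord[i]];
    gr[i] = group[ord[i]];
  }
  return logrank_p_sorted(t.data(), ev.data(), gr.data(), n);
}

// Per-row fuzzy bipartition + log-rank p-value. `scores` has one row per
// unit (gene or gene set), one column per sample, aligned with time/event.
// NA is returned for degenerate rows.
// [[Rcpp::export(name = ".row_fuzzy_logrank_cpp")]]
NumericVector row_fuzzy_logrank_cpp(NumericMatrix scores, NumericVector time,
                                    IntegerVector event, double m) {
  const int n = scores.ncol(), R = scores.nrow();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a] < time[b]; });
  std::vector<double> t(n);
  std::vector<int> ev(n);
  for (int i = 0; i < n; ++i) { t[i] = time[ord[i]]; ev[i] = event[ord[i]]; }

  NumericVector out(R);
  std::vector<double> x(n);
  std::vector<int> lab, gr(n);
  double centers[2];
  for (int r = 0; r < R; ++r) {
    for (int i = 0; i < n; ++i) x[i] = scores(r, i);
    if (!fcm2(x.data(), n, m, lab, centers)) {
      out[r] = NA_REAL;
      continue;
    }
    for (int i = 0; i < n; ++i) gr[i] = lab[ord[i]];
    out[r] = logrank_p_sorted(t.data(), ev.data(), gr.data(), n);
  }
  return out;
}

// The MSS screen. set_scores: one row per candidate gene set, one column per
// sample (the set's mean heating score in that sample). subsets: list of
// 1-based sample index vectors (the random netMatrix sets). A set passes a
// subset when the fuzzy bipartition of its scores splits survival at
// p < alpha; it is retained when it passes on strictly more than
// pass_fraction of the subsets. With early_stop the subset loop exits as
// soon as the set has accumulated too many failures to be retained, so
// retained sets always carry complete per-subset p-value rows. With
// return_pvals the p-value matrix is kept (NA where unevaluated; needed to
// re-apply tighter cutoffs to the retained sets).
// [[Rcpp::export(name = ".screen_sets_cpp")]]
List screen_sets_cpp(NumericMatrix set_scores, List subsets,
                     NumericVector time, IntegerVector event, double m,
                     double alpha, double pass_fraction, bool early_stop,
                     bool return_pvals) {
  const int n_sets = set_scores.nrow();
  const int S = subsets.size();
  // Precompute per-subset sample order by ascending time.
  std::vector<std::vector<int>> sub_idx(S);   // original 0-based, time-sorted
  std::vector<std::vector<double>> sub_t(S);
  std::vector<std::vector<int>> sub_ev(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector ix = subsets[s];
    int ns = ix.size();
    std::vector<int> idx(ns);
    for (int i = 0; i < ns; ++i) idx[i] = ix[i] - 1;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return time[a] < time[b]; });
    sub_idx[s] = idx;
    sub_t[s].resize(ns);
    sub_ev[s].resize(ns);
    for (int i = 0; i < ns; ++i) {
      sub_t[s][i] = time[idx[i]];
      sub_ev[s][i] = event[idx[i]];
    }
  }
  const int need = (int)std::floor(pass_fraction * S + 1e-9) + 1; // strict >
  LogicalVector retained(n_sets);
  IntegerVector passes(n_sets), evaluated(n_sets);
  NumericMatrix pvals;
  if (return_pvals) {
    pvals = NumericMatrix(n_sets, S);
    std::fill(pvals.begin(), pvals.end(), NA_REAL);
  }

  std::vector<double> x;
  std::vector<int> lab, gr;
  double centers[2];
  for (int r = 0; r < n_sets; ++r) {
    int pass = 0, fail = 0;
    int s = 0;
    for (; s < S; ++s) {
      const std::vector<int>& idx = sub_idx[s];
      const int ns = (int)idx.size();
      x.resize(ns); gr.resize(ns);
      // values in subset order (unsorted) for clustering
      for (int i = 0; i < ns; ++i) x[i] = set_scores(r, idx[i]);
      double p;
      if (!fcm2(x.data(), ns, m, lab, centers)) {
        p = 1.0;  // degenerate: cannot split
      } else {
        for (int i = 0; i < ns; ++i) gr[i] = lab[i];
        p = logrank_p_sorted(sub_t[s].data(), sub_ev[s].data(), gr.data(), ns);
      }
      if (return_pvals) pvals(r, s) = p;
      if (p < alpha) ++pass; else ++fail;
      if (early_stop && fail > S - need) { ++s; break; }
    }
    passes[r] = pass;
    evaluated[r] = s;
    retained[r] = pass >= need;
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["retained"] = retained, _["passes"] = passes,
                          _["evaluated"] = evaluated, _["need"] = need);
  if (return_pvals) out["pvals"] = pvals;
  return out;
}
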