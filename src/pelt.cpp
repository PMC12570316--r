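#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact penalized least-squares segmentation (optimal partitioning with
// PELT pruning; identical solution to the unpruned dynamic program).
// Cost of a segment is its sum of squared deviations from the segment
// mean; each additional segment costs `lambda`.  Ties are broken toward
// fewer segments.  Returns 0-based indices of the first element of each
// segment after the first.
// [[Rcpp::export(name = ".pelt_sse")]]
IntegerVector pelt_sse(NumericVector y, double lambda, int min_size) {
  const int n = y.size();
  if (n < 1) return IntegerVector(0);
  if (min_size < 1) min_size = 1;

  std::vector<double> S(n + 1, 0.0), SS(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + y[i];
    SS[i + 1] = SS[i] + y[i] * y[i];
  }
  auto seg_cost = [&](int a, int b) {  // cost of y[a..b-1], b > a
    double s = S[b] - S[a];
    return SS[b] - SS[a] - s * s / (b - a);
  };

  std::vector<double> F(n + 1, R_PosInf);
  std::vector<int> prev(n + 1, 0), nseg(n + 1, 0);
  F[0] = -lambda;
  std::vector<int> cands;
  cands.reserve(256);

  for (int t = min_size; t <= n; ++t) {
    if (t - min_size >= 0 &&
        (t - min_size == 0 || t - 2 * min_size >= 0)) {
      // tau becomes usable once both the new segment (tau..t) and, for
      // tau > 0, the prefix ending at tau can be at least min_size long
      int tau = t - min_size;
      if (tau == 0 || F[tau] < R_PosInf) cands.push_back(tau);
    }
    double best = R_PosInf;
    int best_tau = -1, best_nseg = 0;
    for (size_t i = 0; i < cands.size(); ++i) {
      int tau = cands[i];
      double c = F[tau] + seg_cost(tau, t) + lambda;
      double tol = 1e-9 * (1.0 + std::abs(c));
      if (c < best - tol ||
          (std::abs(c - best) <= tol && nseg[tau] + 1 < best_nseg)) {
        best = c;
        best_tau = tau;
        best_nseg = nseg[tau] + 1;
      }
    }
    F[t] = best;
    prev[t] = best_tau;
    nseg[t] = best_nseg;
    // PELT pruning: tau cannot be optimal for any t' > t
    std::vector<int> keep;
    keep.reserve(cands.size());
    for (size_t i = 0; i < cands.size(); ++i) {
      int tau = cands[i];
      if (F[tau] + seg_cost(tau, t) <= F[t] + 1e-9 * (1.0 + std::abs(F[t])))
        keep.push_back(tau);
    }
    cands.swap(keep);
  }

  std::vector<int> bounds;
  int t = n;
  while (t > 0) {
    int tau = prev[t];
    if (tau > 0) bounds.push_back(tau);
    t = tau;
  }
  std::sort(bounds.begin(), bounds.end());
  return wrap(bounds);
}

// Per-base fragment coverage over one contig via a difference array.
// starts/ends are 0-based half-open; returns numeric vector of length L.
// [[Rcpp::export(name = ".frag_coverage")]]
NumericVector frag_coverage(IntegerVector starts, IntegerVector ends,
                            int L) {
  std::vector<double> d(L + 1, 0.0);
  for (int i = 0; i < starts.size(); ++i) {
    int s = std::max(0, starts[i]);
    int e = std::min(L, ends[i]);
    if (s < e) {
      d[s] += 1.0;
      d[e] -= 1.0;
    }
  }
  NumericVector out(L);
  double acc = 0.0;
  for (int i = 0; i < L; ++i) {
    acc += d[i];
    out[i] = acc;
  }
  return out;
}
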