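#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Least-squares change-point recursion over an ordered log2-ratio series.
//
// cost(i, j) is the within-segment sum of squared deviations from the
// segment mean, computed from prefix sums; long doubles keep the repeated
// subtraction stable enough that the exhaustive-enumeration oracle matches
// to the last bit on short series.
//
// D[m][i] = minimal SSE of partitioning x[i..n] into m segments (suffix
// recursion).  Running the recursion on suffixes lets the reconstruction
// walk forward and pick, at each step, the smallest feasible segment end
// that still attains the optimum -- i.e. the lexicographically smallest
// breakpoint vector among ties.

static inline long double seg_cost(const std::vector<long double> &S1,
                                   const std::vector<long double> &S2,
                                   int i, int j) {
  long double s = S1[j] - S1[i - 1];
  long double s2 = S2[j] - S2[i - 1];
  long double c = s2 - s * s / (long double)(j - i + 1);
  return c > 0 ? c : 0;
}

// [[Rcpp::export(name = ".dp_segment_all")]]
List dp_segment_all(NumericVector x, int kmax) {
  const int n = x.size();
  if (n < 1) stop("empty series");
  if (kmax < 1 || kmax > n) stop("kmax must be in 1..length(series)");
  const long double INF = std::numeric_limits<long double>::infinity();

  std::vector<long double> S1(n + 1, 0.0L), S2(n + 1, 0.0L);
  for (int i = 1; i <= n; ++i) {
    S1[i] = S1[i - 1] + (long double)x[i - 1];
    S2[i] = S2[i - 1] + (long double)x[i - 1] * (long double)x[i - 1];
  }

  // D[m][i]: i ranges 1..n+1 (n+1 = empty suffix, only valid for m = 0)
  std::vector< std::vector<long double> > D(
      kmax + 1, std::vector<long double>(n + 2, INF));
  for (int i = 1; i <= n; ++i) D[1][i] = seg_cost(S1, S2, i, n);
  for (int m = 2; m <= kmax; ++m) {
    for (int i = 1; i <= n - m + 1; ++i) {
      long double best = INF;
      // first segment i..e; leave at least m-1 probes for the rest
      for (int e = i; e <= n - m + 1; ++e) {
        long double c = seg_cost(S1, S2, i, e) + D[m - 1][e + 1];
        if (c < best) best = c;
      }
      D[m][i] = best;
    }
  }

  NumericVector sse(kmax);
  List breaks(kmax);
  for (int k = 1; k <= kmax; ++k) {
    sse[k - 1] = (double)D[k][1];
    IntegerVector b(k - 1);
    int pos = 1;
    for (int m = k; m > 1; --m) {
      long double best = INF;
      int best_e = -1;
      for (int e = pos; e <= n - m + 1; ++e) {
        long double c = seg_cost(S1, S2, pos, e) + D[m - 1][e + 1];
        if (c < best) { best = c; best_e = e; }
      }
      b[k - m] = best_e;  // 1-based index of the segment's last probe
      pos = best_e + 1;
    }
    breaks[k - 1] = b;
  }
  return List::create(_["sse"] = sse, _["breaks"] = breaks);
}
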