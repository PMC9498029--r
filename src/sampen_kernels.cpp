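#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Chebyshev tolerance check over element offsets [k0, scale) of the templates
// starting at 0-based positions i and j.  Non-strict (<= r): the counting
// algorithms all use the inclusive comparison, and every variant must use the
// same one so their match counts stay bit-identical.  `comps` accumulates the
// number of element comparisons actually executed (early exit on first
// violation), which is the work counter reported to the benchmark layer.
static inline bool cheb_match(const double* x, int i, int j, int k0, int scale,
                              double r, double& comps) {
  for (int k = k0; k < scale; ++k) {
    comps += 1.0;
    if (std::abs(x[i + k] - x[j + k]) > r) return false;
  }
  return true;
}

// Straightforward SampEn counting: all template pairs, both scales.
// Counts are ordered-pair, self-matches excluded (enumerates i != j directly,
// equivalent to counting self pairs and subtracting them afterwards).
// [[Rcpp::export]]
List cpp_sf_counts(NumericVector x, int m, double r) {
  const int N = x.size();
  const double* px = REAL(x);
  const int nT1 = N - m + 1;  // templates at scale m   (0-based starts 0..N-m)
  const int nT2 = N - m;      // templates at scale m+1 (0-based starts 0..N-m-1)
  double count1 = 0.0, count2 = 0.0, comps = 0.0;
  for (int i = 0; i < nT1; ++i) {
    for (int j = i + 1; j < nT1; ++j) {
      if (cheb_match(px, i, j, 0, m, r, comps)) {
        count1 += 2.0;  // (i,j) and (j,i)
        // A scale-(m+1) match is the scale-m match plus the next element;
        // only templates with starts <= N-m-1 exist at scale m+1.
        if (j < nT2 && cheb_match(px, i, j, m, m + 1, r, comps))
          count2 += 2.0;
      }
    }
  }
  return List::create(_["count1"] = count1, _["count2"] = count2,
                      _["comparisons"] = comps);
}

// Bucket-assisted counting.  `bucket_of` holds the 0-based bucket id of each
// template (computed from the shifted template sums), `nb` the number of
// allocated buckets.  Every ordered candidate pair whose buckets are within
// m of each other is checked; self pairs are visited and removed by the
// printed corrections (count1 -= N-m+1, count2 -= N-m).
// [[Rcpp::export]]
List cpp_ba_counts(NumericVector x, IntegerVector bucket_of, int nb, int m,
                   double r) {
  const int N = x.size();
  const double* px = REAL(x);
  const int nT1 = N - m + 1;
  const int nT2 = N - m;
  std::vector< std::vector<int> > buckets(nb);
  for (int i = 0; i < nT1; ++i) buckets[bucket_of[i]].push_back(i);

  double count1 = 0.0, count2 = 0.0, comps = 0.0;
  for (int ib = 0; ib < nb; ++ib) {
    if (buckets[ib].empty()) continue;
    const int lo = std::max(0, ib - m);
    const int hi = std::min(nb, ib + m + 1);
    for (int jb = lo; jb < hi; ++jb) {
      if (buckets[jb].empty()) continue;
      for (size_t a = 0; a < buckets[ib].size(); ++a) {
        const int i = buckets[ib][a];
        for (size_t b = 0; b < buckets[jb].size(); ++b) {
          const int j = buckets[jb][b];
          if (cheb_match(px, i, j, 0, m, r, comps)) {
            count1 += 1.0;
            if (i < nT2 && j < nT2 &&
                cheb_match(px, i, j, m, m + 1, r, comps))
              count2 += 1.0;
          }
        }
      }
    }
  }
  count1 -= nT1;  // remove self-matches at scale m
  count2 -= nT2;  // remove self-matches at scale m+1
  return List::create(_["count1"] = count1, _["count2"] = count2,
                      _["comparisons"] = comps);
}

// Stable indexed sorting with operation counters.
//   bubble: adjacent swap on strict inversion only (stability), early exit on
//           a clean pass; counts comparisons and exchanges.
//   merge:  iterative bottom-up, run width 1,2,4,...; ties taken from the
//           left run (stability); counts element merge steps and layers.
// [[Rcpp::export]]
List cpp_sort_indexed(NumericVector x, std::string algorithm) {
  const int N = x.size();
  std::vector<double> y(x.begin(), x.end());
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  double comparisons = 0.0, exchanges = 0.0, merge_ops = 0.0;
  int layers = 0;

  if (algorithm == "bubble") {
    for (int pass = 0; pass < N - 1; ++pass) {
      bool swapped = false;
      for (int k = 0; k + 1 < N - pass; ++k) {
        comparisons += 1.0;
        if (y[k] > y[k + 1]) {
          std::swap(y[k], y[k + 1]);
          std::swap(idx[k], idx[k + 1]);
          exchanges += 1.0;
          swapped = true;
        }
      }
      if (!swapped) break;
    }
  } else if (algorithm == "merge") {
    std::vector<double> ybuf(N);
    std::vector<int> ibuf(N);
    for (int width = 1; width < N; width *= 2) {
      layers += 1;
      for (int lo = 0; lo < N; lo += 2 * width) {
        const int mid = std::min(lo + width, N);
        const int hi = std::min(lo + 2 * width, N);
        int a = lo, b = mid, k = lo;
        while (a < mid && b < hi) {
          comparisons += 1.0;
          if (y[a] <= y[b]) { ybuf[k] = y[a]; ibuf[k] = idx[a]; ++a; }
          else              { ybuf[k] = y[b]; ibuf[k] = idx[b]; ++b; }
          merge_ops += 1.0; ++k;
        }
        while (a < mid) { ybuf[k] = y[a]; ibuf[k] = idx[a]; ++a; merge_ops += 1.0; ++k; }
        while (b < hi)  { ybuf[k] = y[b]; ibuf[k] = idx[b]; ++b; merge_ops += 1.0; ++k; }
        for (int t = lo; t < hi; ++t) { y[t] = ybuf[t]; idx[t] = ibuf[t]; }
      }
    }
  } else {
    stop("unknown sorting algorithm '%s'", algorithm.c_str());
  }

  IntegerVector index1(N);
  for (int i = 0; i < N; ++i) index1[i] = idx[i] + 1;  // 1-based for R
  return List::create(_["y"] = NumericVector(y.begin(), y.end()),
                      _["index"] = index1,
                      _["comparisons"] = comparisons,
                      _["exchanges"] = exchanges,
                      _["merge_ops"] = merge_ops,
                      _["layers"] = layers);
}

// Lightweight counting on a pre-sorted series.  For each sorted position i,
// scan forward while the sorted-value gap stays within r (any later j fails
// too); surviving pairs with valid template starts get the full Chebyshev
// check.  The first template element is already compared by the gap test
// (y[i] and y[j] are exactly those elements), so the check resumes at
// offset 1.  Unordered tallies are doubled so counts match the ordered-pair
// convention of the straightforward algorithm.
// [[Rcpp::export]]
List cpp_lw_counts(NumericVector y, IntegerVector index1, NumericVector x,
                   int m, double r) {
  const int N = x.size();
  const double* px = REAL(x);
  const double* py = REAL(y);
  const int nT1 = N - m + 1;
  const int nT2 = N - m;
  double tally1 = 0.0, tally2 = 0.0, comps = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      comps += 1.0;  // sorted-gap comparison = first-element comparison
      if (py[j] - py[i] > r) break;
      const int ii = index1[i] - 1;
      const int jj = index1[j] - 1;
      if (ii < nT1 && jj < nT1) {
        if (cheb_match(px, ii, jj, 1, m, r, comps)) {
          tally1 += 1.0;
          if (ii < nT2 && jj < nT2 &&
              cheb_match(px, ii, jj, m, m + 1, r, comps))
            tally2 += 1.0;
        }
      }
    }
  }
  return List::create(_["count1"] = 2.0 * tally1, _["count2"] = 2.0 * tally2,
                      _["comparisons"] = comps);
}

// Per-element forward neighbour counts in a sorted sequence: nn[i] is the
// number of j > i with y[j] - y[i] <= r.  Two-pointer, O(N).
// [[Rcpp::export]]
NumericVector cpp_nn_counts(NumericVector y, double r) {
  const int N = y.size();
  NumericVector nn(N);
  int j = 0;
  for (int i = 0; i < N; ++i) {
    if (j < i + 1) j = i + 1;
    while (j < N && y[j] - y[i] <= r) ++j;
    nn[i] = j - (i + 1);
  }
  return nn;
}
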