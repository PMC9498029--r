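---
title: "Fast sample entropy: algorithms, design parameters, and latency models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast sample entropy: algorithms, design parameters, and latency models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastsampen)
```

## The statistic

Sample entropy (SampEn) measures the irregularity of a one-dimensional time
series `x` of length `N`. Fix an embedding dimension `m` and a tolerance
`r`. The `i`-th template vector at scale `m` is the window
`(x[i], ..., x[i+m-1])`; there are `N - m + 1` of them. Two templates match
when their Chebyshev distance (the maximum absolute element-wise
difference) is within the tolerance. Let `count1` be the number of ordered
template pairs (`i != j`, self-matches excluded) matching at scale `m` and
`count2` the analogous count at scale `m + 1`. The mean match
probabilities are

    B = count1 / ((N - m + 1) * (N - m))
    A = count2 / ((N - m)   * (N - m - 1))

and `SampEn = -ln(A / B)`. When `A = 0` no template pair stays similar at
the longer scale and the statistic is undefined; the package returns a
result flagged `defined = FALSE` with a reason string rather than raising
an error, because undefined entropies are an ordinary outcome on short or
widely spaced series. Note the two denominators use template populations
differing by one; we keep them exactly as printed above for comparability
with the hardware-design literature that uses this convention.

Highly regular signals (a constant series, a clean periodic waveform) give
`A = B` and `SampEn = 0`; white noise gives large values. For
physiological work the conventional settings are `m = 2`, `r = 0.15` in
units of the sample standard deviation, and those are the package
defaults.

## Tolerance interpretation and normalization

`sampen_params(r_mode =)` controls what `r` means:

* `"relative_to_sd"` (default): the series is z-normalized internally and
  the effective tolerance is `r` itself (equivalently, `r` times the SD of
  the raw input). SampEn then depends only on the shape of the signal, not
  its units: it is exactly invariant under affine transforms `a*x + b`.
  This normalization is also what makes the bucket statistics below
  comparable across recordings.
* `"absolute"`: the series is used as-is and `r` is in signal units.
  Needed for degenerate inputs (a constant series has no SD to scale by)
  and when tolerances are calibrated externally.

A zero-variance series in relative mode is a degenerate-input error.

## Four algorithms, one answer

All four implementations return bit-identical match counts; they differ
only in how many candidate pairs they examine.

**Straightforward (`sampen_sf`)** compares all `O(N^2)` template pairs.
It is the reference implementation and the ground truth for the others.

**Bucket-assisted (`sampen_ba`)** computes the per-template sums
`X_i = x[i] + ... + x[i+m-1]`, shifts them by `-min + 1` so the smallest
corrected sum is exactly 1, and bins template indices into buckets of
width `r`: index `i` goes to bucket `floor(X_i / r)`, with
`Nb = floor(Xmax / r) + 1` buckets allocated so the maximal sum is always
valid. If two templates match, each element pair differs by at most `r`,
so the sums differ by at most `m*r` and the bucket indices by at most `m`:
scanning only the `2m + 1` neighbouring buckets (`Nnw`) loses no match.
The candidate search visits every ordered pair within the window once,
including self pairs, which are then subtracted (`count1 -= N - m + 1`,
`count2 -= N - m`). Bucket count `Nb` and occupancy `Nc` are the storage
and latency drivers of a hardware port, and are returned as
`$bucket_stats`.

The `+1` in the sum shift is kept verbatim from the published procedure:
it inflates `Nb` by about `1/r` buckets but is part of the design-space
measurements this package reproduces. Likewise `Nb` is printed in the
source material without a rounding rule; we allocate `floor(Xmax/r) + 1`
so the bucket of the maximal sum always exists. Both choices are fixed,
not tunable.

**Lightweight (`sampen_lw`)** sorts the series (keeping original indices)
and scans each sorted position forward only while the sorted-value gap is
within `r`. The gap between sorted values *is* the first-element distance
of the corresponding templates, so every pruned pair is a guaranteed
non-match, and the first element never needs re-checking. Surviving pairs
with valid template starts get the full Chebyshev check. Pairs are
counted once (`j > i`) and the tallies doubled, standardizing on the
ordered-pair convention of the straightforward algorithm so counts are
comparable across variants (the factor cancels in `A/B`, so the entropy
itself never depends on this). Two stable sorting back-ends are provided,
matching the two hardware architectures of interest:

* BubbleSort (`algorithm = "bubble"`): adjacent swaps on strict inversions
  only, early exit on a clean pass. The exchange count is measured and
  feeds the sort latency model.
* bottom-up MergeSort (`algorithm = "merge"`): iterative run-doubling
  (widths 1, 2, 4, ...), ties taken from the left run. The number of
  layers is `ceil(log2 N)`.

Stability matters: equal values keep their original relative order, so
results are deterministic and the index array is a well-defined
permutation.

The mean forward-neighbour count `Nn` (`extract_nn`) — how many sorted
successors of an element lie within `r` — is the latency driver of the
lightweight search; the mean over positions is the default summary and
the full per-element distribution is available with `full = TRUE`.

### Scale-(m+1) guard

The printed pseudocode for these algorithms indexes one element past the
last scale-`m` template when extending to scale `m + 1`. The
implementations restrict the `m + 1` comparison to template starts
`<= N - m - 1` (0-based), because only those templates exist at the longer
scale. Similarly, loop bounds are generalized from the usual `m = 2`
presentation to any `m >= 1`.

### Inclusive comparison

Definitions of the Chebyshev criterion alternate between `< r` and
`<= r` in the literature. Internal consistency across the four variants is
what matters for equivalence, so the inclusive `<= r` is used everywhere,
including the tolerance-gap pruning rule of the lightweight scan and the
definition-level oracle in the test suite. For continuous-valued data the
two conventions differ with probability zero.

## Hardware latency models

Cycle-level cost models estimate the execution time of each algorithm on
a clocked device. Per-operation cycle costs are configuration
(`cycle_costs()`, or a flat JSON file via `read_cycle_costs()`); on a real
device they come from synthesis reports, which are out of scope here, so
the defaults are 1 cycle per elementary operation and 0 for every
correction/overhead term — sufficient for relative comparisons between
algorithms.

* Bucket-assisted: `t1 = titer*Nc + r1`, `t2 = t1*Nc + r2`,
  `t3 = t2*Nnw + r3`, total `Nb*t3 + Ti + Ta`. With corrections at zero
  this is `Nb * Nc^2 * titer * Nnw`; the widely used simplified estimate
  `Nb * Nc^2 * titer` is available as `mode = "simplified"` and equals the
  full chain with a unit window. Whether `Nc` should be the mean or the
  maximum occupancy is not fixed by the source formulas; the mean
  (which approximates total work, since `Nc_mean * Nb` equals the number
  of templates) is the default and the maximum is available as the worst
  case via `nc_stat = "max"`.
* BubbleSort: `tcomparison * sum(1..N) + texchange * exchanges +
  bs_r2 * (N-1)`, with the exchange count measured from an actual sort of
  the input. The comparison term is implemented exactly as printed in the
  hardware cost tables (`sum(1..N) = N(N+1)/2`), although the classical
  count is `N(N-1)/2`; we reproduce the published formula rather than
  silently correcting it.
* MergeSort: `Ml = ceil(log2 N)` layers; `tm*N*Ml` element merges plus
  `ts * sum over layers of ceil(N / 2^layer)` subsequence merges plus
  `tl*Ml` layer overhead. The per-layer subsequence counts are reported
  in the estimate's `$details` for inspection; only their sum enters the
  total.
* Lightweight search: `(tc*Nn + c1)*N + c2*N` plus the sorting cycles.

All estimates report cycles, seconds (`cycles / freq`, default 100 MHz)
and an additive breakdown. `estimate_latency_table()` applies the models
row-wise to a design sweep.

## Synthetic inputs

`generate_noisy_sine()` emulates the oversampled quasi-periodic signals
with measurement noise typical of physiological recordings: a unit sine
plus i.i.d. Gaussian noise at a specified SNR (power ratio in dB against
the sine RMS `amplitude/sqrt(2)` — stated explicitly because SNR
conventions vary). The source material for the bucket design-space
measurements does not state the sine's amplitude or sampling density; we
fix amplitude 1 and 50 samples per cycle once — dense sampling gives the
strong adjacent-sample correlation that makes template sums cluster, the
regime the bucket statistics are about — and treat them as the study
conditions rather than tunable knobs.

`generate_ecg_like()` is a synthetic stand-in for real electrocardiograms:
a periodic train of sharp Gaussian-shaped spikes (QRS-like), a slow
baseline oscillation (respiration-like), and additive noise. It
reproduces the features that matter to these algorithms — sharp extremes,
a skewed value distribution that stresses the bucket partition, and
quasi-periodicity — but not real ECG morphology (P/T waves), beat-to-beat
variability, nonstationary baseline wander or electrode artifacts. A
passing equivalence suite on these inputs therefore demonstrates
algorithmic correctness, not clinical validity of any entropy value; on
real recordings the design parameters (`Nb`, `Nc`, `Nn`) must be
re-measured, which is exactly what `sweep_design_params()` is for.

Both generators are bit-reproducible under a fixed `seed` and leave the
caller's RNG stream untouched. Readers and writers for plain-text and CSV
series (`read_series`, `write_series`) round-trip exactly; adapters for
binary waveform-database formats are deliberately out of scope.

## Numerical and degenerate-input choices

* Minimum length `N >= m + 2`, so both probability denominators are
  positive.
* Undefined entropy (`A = 0`) is a flagged result, never an exception.
* Constant series: every template matches, `SampEn = 0` exactly; all sums
  are equal, so the bucket algorithm degrades to a single occupied bucket
  — its published worst case, quadratic like the straightforward loop.
* Ties in sorting: equal values satisfy the inclusive gap rule and
  proceed to the full check; stability makes the outcome deterministic.
* Bucket completeness relies on `|X_i - X_j| <= m*r` for matching
  templates; with floating-point sums this inequality could in principle
  fail by one ulp at the bucket boundary for adversarial values. The
  equivalence suite (hundreds of random, periodic and uniform inputs)
  asserts exact count equality, where this has never been observed.
* Work counters (`comparisons`) count element-level comparisons actually
  executed in the matching phase, including the failing scan step of the
  lightweight pruning loop — a machine-independent complexity measure
  reported by `run_benchmark()` alongside (never instead of) wall-clock
  medians.

## Problem sizes in the test suite

The packaged tests run the full cross-algorithm equivalence grid on ~210
generated inputs with lengths 10–2,000 (noisy sine at SNR 5–100 dB,
ECG-like, uniform noise), the definition-level brute-force oracle up to
length 300, sorting property checks on 1,000 random multisets, and the
bucket design-parameter sweep on lengths 100–20,000 (bucket construction
is linear in `N`, so the long lengths are cheap). These sizes were chosen
to exercise every algorithmic regime — dense matches, no matches,
saturated buckets — while keeping the default test run fast.

## Known limitations

* The bucket-assisted and lightweight searches are output-sensitive: on
  adversarial inputs (all template sums equal; all values within `r`)
  they degrade to the quadratic behaviour of the straightforward loop.
* Match counts grow like `N^2`; they are held in doubles, exact up to
  `2^53`, which bounds supported lengths far beyond practical use.
* The latency models estimate cycle counts from operation counts; they do
  not model pipelining, memory-port contention or synthesis optimizations,
  so they rank algorithms and scale trends rather than predict absolute
  device timings.
* Only BubbleSort and MergeSort back-ends are provided; other sorts would
  change only the sorting-stage statistics, not the entropy.
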