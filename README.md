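# fastsampen

Sample entropy (SampEn) is a standard measure of the irregularity of a
physiological time series — heart-rate and ECG complexity analysis being
the canonical uses. For a series `x` of length `N`, embedding dimension
`m` and tolerance `r`, count the ordered pairs of length-`m` template
vectors whose Chebyshev distance is within `r` (`count1`, self-matches
excluded) and the same at length `m + 1` (`count2`); then

    B = count1 / ((N - m + 1)(N - m))
    A = count2 / ((N - m)(N - m - 1))
    SampEn = -ln(A / B)        (undefined when A = 0)

The direct computation is `O(N^2)`, which is what makes SampEn awkward in
real time and expensive on long recordings, and what motivates both
accelerated algorithms and hardware (FPGA-style) ports. This package is
for people studying or deploying those accelerations: it provides

* **four implementations with identical match counts** — the
  straightforward double loop (`sampen_sf`), a bucket-assisted search that
  bins template sums into width-`r` buckets and only compares neighbouring
  buckets (`sampen_ba`), and a lightweight search over a pre-sorted series
  that stops scanning once the sorted-value gap exceeds `r`, with stable
  BubbleSort or bottom-up MergeSort back-ends (`sampen_lw`);
* **hardware design-parameter extraction** — bucket count `Nb`, bucket
  occupancy `Nc`, neighbour window `2m + 1`, sorted-neighbour count `Nn`,
  sort exchange counts — the quantities that size the memory and drive the
  latency of a hardware implementation (`sweep_design_params`);
* **cycle-level latency models** for each algorithm
  (`estimate_ba_latency`, `estimate_bs_latency`, `estimate_ms_latency`,
  `estimate_lw_latency`, `cycle_costs`);
* **synthetic input generators** — noisy sinusoids on an SNR grid and
  ECG-like quasi-periodic spike trains (`generate_noisy_sine`,
  `generate_ecg_like`) — plus plain-text/CSV series IO;
* **verification and benchmarking drivers** (`run_equivalence_suite`,
  `run_benchmark`) and a thin command-line front end
  (`inst/cli/fastsampen-cli.R`).

Defaults are the field conventions: `m = 2`, `r = 0.15` relative to the
sample SD (the series is z-normalized internally; use
`r_mode = "absolute"` for raw units).

## Worked example

```r
library(fastsampen)

x <- generate_noisy_sine(2000, snr_db = 20, seed = 1)

res <- sampen_ba(x)        # bucket-assisted; identical value to sampen_sf(x)
res
#> SampEn (ba): 0.710206 nats
#>   N = 2000, m = 2, r_eff = 0.15
#>   B = 0.0479559 (count1 = 191536), A = 0.0235724 (count2 = 94054)

res$bucket_stats           # hardware design parameters of this input
#> Bucket stats: Nb = 49, Nc_max = 118, Nc_mean = 40.796, Nnw = 5
```

Of the 191,536 ordered template pairs matching at scale 2, a fraction
`A/B = 0.49` still match at scale 3, giving `-ln(0.49) = 0.71` nats — a
fairly regular signal, as expected for a sine with mild (20 dB) noise.
The bucket table that accelerated the search used 49 buckets with a mean
occupancy of ~41 candidates.

The lightweight variant returns the same entropy plus sorting statistics,
which feed the latency models:

```r
lw <- sampen_lw(x, algorithm = "merge")
lw$sort_stats
#> Sort stats (merge): comparisons = 17483, merge_ops = 22000, layers = 11

estimate_ba_latency(res$bucket_stats, cycle_costs(titer = 2))
#> Latency estimate (ba_full): 815510 cycles = 0.0081551 s at 1e+08 Hz
#>   breakdown: search = 815510, init = 0, assign = 0

estimate_lw_latency(2000, lw$nn_mean, estimate_ms_latency(2000, cycle_costs()),
                    cycle_costs(tc = 2))
#> Latency estimate (lw): 445488 cycles = 0.00445488 s at 1e+08 Hz
#>   breakdown: search = 421476, sort = 24012
```

So at 100 MHz and these (unit) cycle costs, the MergeSort-lightweight
architecture would finish this input in ~4.5 ms, about half the
bucket-assisted estimate — with the caveat that bucket-assisted latency
depends strongly on how evenly the data distribute over buckets.

The command-line front end wraps the same functions:

```sh
Rscript inst/cli/fastsampen-cli.R compute --n 2000 --snr 20 --seed 1 --algorithm ba
Rscript inst/cli/fastsampen-cli.R verify --lengths 10,100,500 --snr 5,20,100 --seeds 3
Rscript inst/cli/fastsampen-cli.R sweep --lengths 100,500,2000,20000 --snr 5,10,20,50,100 --out sweep.csv
Rscript inst/cli/fastsampen-cli.R estimate-latency --sweep sweep.csv --costs costs.json
```

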