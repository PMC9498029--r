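Package: fastsampen
Title: Fast Sample Entropy Algorithms with Hardware Latency Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Sample entropy (SampEn) quantifies the irregularity of a
    physiological time series as the negative log conditional probability
    that template vectors similar for m points remain similar for m+1
    points.  The straightforward computation is quadratic in the series
    length, which limits real-time use on long electrocardiogram or other
    biomedical recordings.  This package provides four implementations
    that produce identical match counts: the straightforward double loop,
    a bucket-assisted variant that prunes candidate pairs by binning
    template sums, and two lightweight variants that pre-sort the series
    (stable BubbleSort or bottom-up MergeSort) and stop scanning once the
    sorted-value gap exceeds the tolerance.  It also extracts the design
    parameters that drive hardware ports of these algorithms (bucket
    count, bucket occupancy, sorted-neighbour counts, sort exchange
    counts), implements cycle-level latency estimation models for each
    algorithm, and generates synthetic inputs (noisy sinusoids over an
    SNR grid and ECG-like quasi-periodic signals) for validation,
    benchmarking and design-space sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
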