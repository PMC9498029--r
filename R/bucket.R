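# Bucket-assisted SampEn: sum-based bucketing, neighbour-window candidate
# search, and extraction of the hardware design parameters Nb and Nc.

#' Shifted template sums
#'
#' Computes the per-template sums `X_i = sum(x[i..i+m-1])` and shifts them by
#' `-min + 1` so the smallest corrected sum is exactly 1 (this keeps bucket
#' indices positive; the shift is part of the published algorithm and is
#' reflected in the bucket counts).
#'
#' @param x numeric series of length at least `m`.
#' @param m embedding dimension.
#' @return An object of class `sum_series`: `sums` (corrected, length
#'   `N - m + 1`), `offset_applied` (the shift `1 - min(raw sums)`), `xmax`
#'   (maximum corrected sum).
#' @examples
#' template_sums(c(0, 10, 20, 30, 40), 2)$sums  # 1 21 41 61
#' @export
template_sums <- function(x, m) {
  x <- check_series(x)
  stopifnot(m >= 1, m == as.integer(m))
  n <- length(x)
  if (n < m) stop(sprintf("series shorter than m: N = %d, m = %d", n, m))
  raw <- as.numeric(stats::filter(x, rep(1, m), sides = 1))[m:n]
  offset <- 1 - min(raw)
  sums <- raw + offset
  structure(list(sums = sums, offset_applied = offset, xmax = max(sums)),
            class = "sum_series")
}

#' Build the bucket table
#'
#' Assigns each template index to bucket `floor(X_i / r_eff)` of its shifted
#' sum and allocates `Nb = floor(Xmax / r_eff) + 1` buckets, so the template
#' with the maximal sum always has a valid bucket.
#'
#' @param sums a `sum_series` from [template_sums()].
#' @param r_eff effective tolerance (also the bucket width).
#' @return An object of class `bucket_table`: `nb` (bucket count),
#'   `assignment` (0-based bucket id per template), `buckets` (list of
#'   1-based template indices per bucket), `occupancies`, `bucket_width`,
#'   `n_templates`.
#' @export
build_buckets <- function(sums, r_eff) {
  stopifnot(inherits(sums, "sum_series"), is.numeric(r_eff), r_eff > 0)
  nb <- as.integer(floor(sums$xmax / r_eff)) + 1L
  assignment <- as.integer(floor(sums$sums / r_eff))
  occupancies <- tabulate(assignment + 1L, nbins = nb)
  buckets <- split(seq_along(assignment),
                   factor(assignment, levels = 0:(nb - 1L)))
  names(buckets) <- NULL
  structure(list(nb = nb, assignment = assignment, buckets = buckets,
                 occupancies = occupancies, bucket_width = as.numeric(r_eff),
                 n_templates = length(assignment)),
            class = "bucket_table")
}

#' Bucket design statistics
#'
#' Summarizes a bucket table into the quantities that drive the hardware
#' design: the bucket count `Nb`, the maximum and mean occupancy `Nc`, and
#' the neighbour-window width `Nnw = 2m + 1` (a template can only match
#' candidates within `m` buckets, because matching templates have sums
#' within `m * r_eff`).  The mean occupancy is taken over all allocated
#' buckets, so `Nc_mean * Nb` equals the number of templates.
#'
#' @param table a `bucket_table` from [build_buckets()].
#' @param m embedding dimension.
#' @return An object of class `bucket_stats` with fields `nb`, `nc_max`,
#'   `nc_mean`, `nnw`.
#' @export
bucket_stats <- function(table, m) {
  stopifnot(inherits(table, "bucket_table"), m >= 1, m == as.integer(m))
  structure(list(nb = table$nb,
                 nc_max = max(table$occupancies),
                 nc_mean = table$n_templates / table$nb,
                 nnw = 2L * as.integer(m) + 1L),
            class = "bucket_stats")
}

#' @export
print.bucket_stats <- function(x, ...) {
  cat(sprintf("Bucket stats: Nb = %d, Nc_max = %d, Nc_mean = %.3f, Nnw = %d\n",
              x$nb, x$nc_max, x$nc_mean, x$nnw))
  invisible(x)
}

#' Bucket-assisted match counting
#'
#' Compares every candidate pair whose buckets lie within `m` of each other
#' (the neighbour window) with the full Chebyshev check at both scales.
#' Because matching templates have sums differing by at most `m * r_eff`,
#' the window prefilter loses no match and the counts equal [sf_counts()]
#' exactly.  Self pairs are visited and removed afterwards, as in the
#' published pseudocode.
#'
#' @param x numeric series the table was built from.
#' @param table a `bucket_table` built from `template_sums(x, m)` with the
#'   same `r_eff`.
#' @param m embedding dimension.
#' @param r_eff effective tolerance.
#' @return A `match_counts` object, identical to `sf_counts(x, m, r_eff)`.
#' @export
ba_counts <- function(x, table, m, r_eff) {
  x <- check_series(x)
  stopifnot(inherits(table, "bucket_table"), m >= 1, m == as.integer(m),
            r_eff > 0)
  check_sampen_length(length(x), m)
  if (table$n_templates != length(x) - m + 1) {
    stop("bucket table does not match the series/template count")
  }
  if (!isTRUE(all.equal(table$bucket_width, r_eff))) {
    stop("bucket table was built with a different tolerance")
  }
  res <- cpp_ba_counts(x, table$assignment, table$nb, as.integer(m),
                       as.numeric(r_eff))
  new_match_counts(res$count1, res$count2, res$comparisons)
}

#' Bucket-assisted sample entropy
#'
#' Accelerates SampEn by binning template sums into width-`r_eff` buckets
#' and only comparing candidates from neighbouring buckets.  Returns the
#' same entropy as [sampen_sf()] together with the bucket design statistics
#' (`Nb`, `Nc`) used for hardware latency estimation.
#'
#' @param x numeric series.
#' @param params a [sampen_params()] object.
#' @return A `sampen_result` with an extra `$bucket_stats` field.
#' @examples
#' x <- generate_noisy_sine(500, snr_db = 20, seed = 1)
#' res <- sampen_ba(x)
#' res$bucket_stats
#' @export
sampen_ba <- function(x, params = sampen_params()) {
  prep <- prepare_series(x, params)
  check_sampen_length(length(prep$x), params$m)
  sums <- template_sums(prep$x, params$m)
  table <- build_buckets(sums, prep$r_eff)
  counts <- ba_counts(prep$x, table, params$m, prep$r_eff)
  res <- entropy_from_counts(counts, length(prep$x), params$m)
  res$r_eff <- prep$r_eff
  res$algorithm <- "ba"
  res$bucket_stats <- bucket_stats(table, params$m)
  res
}
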