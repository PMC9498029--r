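# Lightweight SampEn: stable indexed sorting (BubbleSort / bottom-up
# MergeSort), first-element pruning on the sorted sequence, Nn extraction.

#' Stable indexed sort with operation counters
#'
#' Sorts the series ascending while tracking each element's original
#' position, using either adjacent-swap BubbleSort (swaps only on strict
#' inversion, early exit on a clean pass) or iterative bottom-up MergeSort
#' (ties taken from the left run).  Both are stable, so equal values keep
#' their original relative order and all downstream counts are
#' deterministic.
#'
#' @param x numeric series.
#' @param algorithm `"merge"` (default) or `"bubble"`.
#' @return An object of class `sorted_series`: `y` (sorted values), `index`
#'   (1-based original positions, `y[k] == x[index[k]]`), and `stats`, a
#'   `sort_stats` object with `comparisons`, `exchanges` (BubbleSort),
#'   `merge_ops` and `layers` (MergeSort).
#' @examples
#' sort_indexed(c(4, 3, 2, 1), "bubble")$stats$exchanges  # 6
#' @export
sort_indexed <- function(x, algorithm = c("merge", "bubble")) {
  algorithm <- match.arg(algorithm)
  x <- check_series(x)
  res <- cpp_sort_indexed(x, algorithm)
  stats <- structure(list(algorithm = algorithm,
                          comparisons = res$comparisons,
                          exchanges = if (algorithm == "bubble") res$exchanges else NA_real_,
                          merge_ops = if (algorithm == "merge") res$merge_ops else NA_real_,
                          layers = if (algorithm == "merge") res$layers else NA_integer_),
                     class = "sort_stats")
  structure(list(y = res$y, index = res$index, stats = stats),
            class = "sorted_series")
}

#' @export
print.sort_stats <- function(x, ...) {
  cat(sprintf("Sort stats (%s): comparisons = %.0f", x$algorithm, x$comparisons))
  if (x$algorithm == "bubble") cat(sprintf(", exchanges = %.0f", x$exchanges))
  if (x$algorithm == "merge") {
    cat(sprintf(", merge_ops = %.0f, layers = %d", x$merge_ops, x$layers))
  }
  cat("\n")
  invisible(x)
}

check_sorted_series <- function(sorted, x) {
  if (!inherits(sorted, "sorted_series")) {
    stop("`sorted` must come from sort_indexed()")
  }
  if (length(sorted$y) != length(x) ||
      !identical(as.numeric(x[sorted$index]), as.numeric(sorted$y))) {
    stop("`sorted` was not built from this series")
  }
}

#' Lightweight match counting on a sorted series
#'
#' For each sorted position the forward scan stops at the first neighbour
#' whose sorted-value gap exceeds `r_eff`: the sorted order guarantees every
#' later neighbour fails too, and a skipped pair cannot match at any scale
#' because its first template elements already differ by more than the
#' tolerance.  Surviving pairs with valid template starts get the full
#' Chebyshev check at scale `m`, then `m + 1`.  Unordered tallies are
#' doubled so the result equals [sf_counts()] exactly.
#'
#' @param sorted a `sorted_series` built from `x` with [sort_indexed()].
#' @param x the raw (or normalized) series.
#' @param m embedding dimension.
#' @param r_eff effective tolerance.
#' @return A `match_counts` object, identical to `sf_counts(x, m, r_eff)`.
#' @export
lw_counts <- function(sorted, x, m, r_eff) {
  x <- check_series(x)
  stopifnot(m >= 1, m == as.integer(m), r_eff > 0)
  check_sampen_length(length(x), m)
  check_sorted_series(sorted, x)
  res <- cpp_lw_counts(sorted$y, sorted$index, x, as.integer(m),
                       as.numeric(r_eff))
  new_match_counts(res$count1, res$count2, res$comparisons)
}

#' Sorted-neighbour count Nn
#'
#' Mean (over sorted positions) number of forward neighbours within `r_eff`
#' in the sorted sequence - the quantity that drives the similarity-search
#' latency of the lightweight algorithm.
#'
#' @param sorted a `sorted_series` from [sort_indexed()].
#' @param r_eff effective tolerance.
#' @param full if `TRUE`, return the per-element forward counts instead of
#'   their mean.
#' @return Mean Nn (scalar), or the full per-element vector when
#'   `full = TRUE`.
#' @examples
#' extract_nn(sort_indexed(rep(1, 10)), 0.2)  # (N-1)/2 = 4.5
#' @export
extract_nn <- function(sorted, r_eff, full = FALSE) {
  if (!inherits(sorted, "sorted_series")) {
    stop("`sorted` must come from sort_indexed()")
  }
  stopifnot(r_eff > 0)
  nn <- cpp_nn_counts(sorted$y, as.numeric(r_eff))
  if (full) nn else mean(nn)
}

#' Lightweight sample entropy
#'
#' Pre-sorts the series so that candidate template pairs are contiguous in
#' value, then prunes the similarity search by the sorted-value gap.
#' Returns the same entropy as [sampen_sf()] together with the sorting
#' statistics used for hardware latency estimation.
#'
#' @param x numeric series.
#' @param params a [sampen_params()] object.
#' @param algorithm sorting back-end, `"merge"` (default) or `"bubble"`.
#' @return A `sampen_result` with extra `$sort_stats` and `$nn_mean` fields.
#' @examples
#' x <- generate_noisy_sine(500, snr_db = 20, seed = 1)
#' sampen_lw(x, algorithm = "bubble")
#' @export
sampen_lw <- function(x, params = sampen_params(),
                      algorithm = c("merge", "bubble")) {
  algorithm <- match.arg(algorithm)
  prep <- prepare_series(x, params)
  check_sampen_length(length(prep$x), params$m)
  sorted <- sort_indexed(prep$x, algorithm)
  counts <- lw_counts(sorted, prep$x, params$m, prep$r_eff)
  res <- entropy_from_counts(counts, length(prep$x), params$m)
  res$r_eff <- prep$r_eff
  res$algorithm <- if (algorithm == "bubble") "bs_lw" else "ms_lw"
  res$sort_stats <- sorted$stats
  res$nn_mean <- extract_nn(sorted, prep$r_eff)
  res
}
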