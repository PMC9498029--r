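# Core SampEn: template matching, straightforward counting, counts -> entropy.

new_match_counts <- function(count1, count2, comparisons = NA_real_) {
  structure(list(count1 = as.numeric(count1), count2 = as.numeric(count2),
                 self_corrected = TRUE, comparisons = as.numeric(comparisons)),
            class = "match_counts")
}

#' @export
print.match_counts <- function(x, ...) {
  cat(sprintf("Match counts (ordered pairs, self-matches removed): count1 = %.0f, count2 = %.0f\n",
              x$count1, x$count2))
  invisible(x)
}

#' Chebyshev template match
#'
#' Tests whether the two length-`scale` template vectors starting at 1-based
#' positions `i` and `j` of `x` match: the maximum absolute element-wise
#' difference (Chebyshev / maximum norm) must not exceed `r_eff`.  The
#' comparison is non-strict, consistently with the counting algorithms.
#'
#' @param x numeric series.
#' @param i,j 1-based start positions of the two templates.
#' @param scale template length (positive integer).
#' @param r_eff effective tolerance in the units of `x`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' template_match(c(1.0, 1.1, 2.0, 1.05, 1.12), 1, 4, 2, 0.15)  # TRUE
#' @export
template_match <- function(x, i, j, scale, r_eff) {
  x <- check_series(x)
  n <- length(x)
  stopifnot(length(i) == 1L, length(j) == 1L, length(scale) == 1L,
            scale >= 1, r_eff > 0)
  if (i < 1 || j < 1 || i + scale - 1 > n || j + scale - 1 > n) {
    stop(sprintf("template start out of range: i = %d, j = %d, scale = %d, N = %d",
                 as.integer(i), as.integer(j), as.integer(scale), n))
  }
  ks <- seq_len(scale) - 1L
  max(abs(x[i + ks] - x[j + ks])) <= r_eff
}

check_sampen_length <- function(n, m) {
  if (n < m + 2) {
    stop(sprintf("series too short: N = %d but N >= m + 2 = %d is required",
                 n, m + 2L))
  }
}

#' Straightforward SampEn match counting
#'
#' Counts ordered template-pair matches at scales `m` and `m + 1` by
#' exhaustive comparison of all pairs (the quadratic reference algorithm).
#' Self-matches are excluded, as SampEn requires.
#'
#' @param x numeric series (already normalized if desired; `r_eff` is in the
#'   units of `x`).
#' @param m embedding dimension.
#' @param r_eff effective tolerance.
#' @return A `match_counts` object with fields `count1` (scale `m`),
#'   `count2` (scale `m + 1`), `self_corrected = TRUE` and `comparisons`
#'   (element comparisons performed, for complexity profiling).
#' @examples
#' sf_counts(rep(5, 5), 2, 0.1)   # constant series: all pairs match
#' @export
sf_counts <- function(x, m, r_eff) {
  x <- check_series(x)
  stopifnot(m >= 1, m == as.integer(m), r_eff > 0)
  check_sampen_length(length(x), m)
  res <- cpp_sf_counts(x, as.integer(m), as.numeric(r_eff))
  new_match_counts(res$count1, res$count2, res$comparisons)
}

new_sampen_result <- function(B, A, n, m, r_eff, counts, algorithm) {
  defined <- A > 0
  structure(list(
    value = if (defined) -log(A / B) else NA_real_,
    defined = defined,
    reason = if (defined) NA_character_ else "no m+1-scale match",
    A = A, B = B,
    count1 = counts$count1, count2 = counts$count2,
    comparisons = counts$comparisons,
    N = n, m = m, r_eff = r_eff,
    algorithm = algorithm
  ), class = "sampen_result")
}

#' @export
print.sampen_result <- function(x, ...) {
  cat(sprintf("SampEn (%s): %s\n", x$algorithm,
              if (x$defined) sprintf("%.6f nats", x$value)
              else sprintf("undefined (%s)", x$reason)))
  cat(sprintf("  N = %d, m = %d, r_eff = %g\n", x$N, x$m, x$r_eff))
  cat(sprintf("  B = %.6g (count1 = %.0f), A = %.6g (count2 = %.0f)\n",
              x$B, x$count1, x$A, x$count2))
  invisible(x)
}

#' Convert match counts to sample entropy
#'
#' Computes the mean match probabilities
#' `B = count1 / ((N - m + 1)(N - m))` and
#' `A = count2 / ((N - m)(N - m - 1))` and the entropy `-ln(A/B)`.  When no
#' scale-(m+1) match exists (`A = 0`) the result is flagged undefined rather
#' than raising an error.
#'
#' @param counts a self-corrected `match_counts` object (see [sf_counts()]).
#' @param n series length.
#' @param m embedding dimension.
#' @return A `sampen_result` with fields `value`, `defined`, `reason`, `A`,
#'   `B`, the counts and the problem dimensions.
#' @examples
#' entropy_from_counts(sf_counts(rep(5, 5), 2, 0.1), n = 5, m = 2)  # 0
#' @export
entropy_from_counts <- function(counts, n, m) {
  if (!inherits(counts, "match_counts") || !isTRUE(counts$self_corrected)) {
    stop("`counts` must be a self-corrected match_counts object")
  }
  stopifnot(m >= 1, m == as.integer(m))
  check_sampen_length(n, m)
  B <- counts$count1 / ((n - m + 1) * (n - m))
  A <- counts$count2 / ((n - m) * (n - m - 1))
  new_sampen_result(B, A, as.integer(n), as.integer(m), NA_real_, counts,
                    algorithm = "counts")
}

#' Straightforward sample entropy
#'
#' The quadratic reference implementation: every template pair is compared
#' at both scales.  All accelerated variants in this package reproduce its
#' match counts exactly.
#'
#' @param x numeric series.
#' @param params a [sampen_params()] object.
#' @return A `sampen_result`.
#' @examples
#' x <- generate_noisy_sine(200, snr_db = 20, seed = 1)
#' sampen_sf(x)
#' @export
sampen_sf <- function(x, params = sampen_params()) {
  prep <- prepare_series(x, params)
  check_sampen_length(length(prep$x), params$m)
  counts <- sf_counts(prep$x, params$m, prep$r_eff)
  res <- entropy_from_counts(counts, length(prep$x), params$m)
  res$r_eff <- prep$r_eff
  res$algorithm <- "sf"
  res
}

#' Sample entropy by any algorithm
#'
#' Front door dispatching to the straightforward (`"sf"`), bucket-assisted
#' (`"ba"`) or lightweight (`"bs_lw"` BubbleSort, `"ms_lw"` MergeSort)
#' implementation.  All four produce identical match counts and entropy.
#'
#' @param x numeric series.
#' @param params a [sampen_params()] object.
#' @param algorithm one of `"sf"`, `"ba"`, `"bs_lw"`, `"ms_lw"`.
#' @return A `sampen_result`; the BA result carries `$bucket_stats`, the LW
#'   results carry `$sort_stats`.
#' @examples
#' x <- generate_noisy_sine(300, snr_db = 20, seed = 7)
#' sampen(x, algorithm = "ms_lw")
#' @export
sampen <- function(x, params = sampen_params(),
                   algorithm = c("sf", "ba", "bs_lw", "ms_lw")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         sf = sampen_sf(x, params),
         ba = sampen_ba(x, params),
         bs_lw = sampen_lw(x, params, algorithm = "bubble"),
         ms_lw = sampen_lw(x, params, algorithm = "merge"))
}
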