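# Cycle-level latency estimation for hardware ports of the SampEn
# algorithms.  Cycle costs per elementary operation are configuration (on a
# real device they come from synthesis reports); the defaults of 1 cycle per
# operation and 0 for correction/overhead terms give relative comparisons
# between algorithms.

#' Cycle-cost configuration
#'
#' Per-operation cycle costs feeding the latency models.  All costs must be
#' non-negative; correction and overhead terms (`r1_corr`, `r2_corr`,
#' `r3_corr`, `Ti`, `Ta`, `bs_r2`, `c1`, `c2`) default to 0 and the
#' elementary operations to 1 cycle.
#'
#' @param titer cycles per similarity comparison (bucket-assisted search).
#' @param Ti,Ta bucket initiation and assignment overhead cycles.
#' @param r1_corr,r2_corr,r3_corr correction terms of the bucket-assisted
#'   latency chain.
#' @param tcomparison,texchange BubbleSort per-comparison and per-exchange
#'   cycles.
#' @param bs_r2 extra cycles per BubbleSort iteration.
#' @param tm,ts,tl MergeSort per-element-merge, per-subsequence and
#'   per-layer cycles.
#' @param tc cycles per template similarity check in the lightweight search.
#' @param c1,c2 lightweight per-element comparison-setup and memory cycles.
#' @param freq clock frequency in Hz (default 100 MHz).
#' @return An object of class `cycle_costs`.
#' @examples
#' cycle_costs(titer = 3)
#' @export
cycle_costs <- function(titer = 1, Ti = 0, Ta = 0,
                        r1_corr = 0, r2_corr = 0, r3_corr = 0,
                        tcomparison = 1, texchange = 1, bs_r2 = 0,
                        tm = 1, ts = 1, tl = 1,
                        tc = 1, c1 = 0, c2 = 0,
                        freq = 100e6) {
  costs <- list(titer = titer, Ti = Ti, Ta = Ta,
                r1_corr = r1_corr, r2_corr = r2_corr, r3_corr = r3_corr,
                tcomparison = tcomparison, texchange = texchange,
                bs_r2 = bs_r2, tm = tm, ts = ts, tl = tl,
                tc = tc, c1 = c1, c2 = c2, freq = freq)
  for (nm in names(costs)) {
    v <- costs[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("cycle cost `%s` must be a finite number", nm))
    }
    if (v < 0) stop(sprintf("cycle cost `%s` must be non-negative", nm))
  }
  if (freq <= 0) stop("`freq` must be positive")
  structure(lapply(costs, as.numeric), class = "cycle_costs")
}

#' Read cycle costs from a JSON file
#'
#' The file holds a flat object whose keys match the [cycle_costs()]
#' arguments; missing keys keep their defaults, unknown keys are an error.
#'
#' @param path path to a JSON file.
#' @return A `cycle_costs` object.
#' @export
read_cycle_costs <- function(path) {
  vals <- jsonlite::fromJSON(path)
  known <- names(formals(cycle_costs))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop(sprintf("unknown cycle-cost keys: %s", paste(bad, collapse = ", ")))
  }
  do.call(cycle_costs, vals)
}

new_latency_estimate <- function(breakdown, details, freq, algorithm) {
  cycles <- sum(unlist(breakdown))
  structure(list(cycles = cycles, seconds = cycles / freq,
                 breakdown = breakdown, details = details,
                 freq = freq, algorithm = algorithm),
            class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("Latency estimate (%s): %.0f cycles = %.6g s at %.3g Hz\n",
              x$algorithm, x$cycles, x$seconds, x$freq))
  parts <- unlist(x$breakdown)
  cat("  breakdown:", paste(sprintf("%s = %.0f", names(parts), parts),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Bucket-assisted latency estimate
#'
#' Full chain: `t1 = titer*Nc + r1`, `t2 = t1*Nc + r2`, `t3 = t2*Nnw + r3`,
#' total `Nb*t3 + Ti + Ta`.  With all corrections and overheads at zero and
#' a neighbour window of 1 the chain collapses to the simplified product
#' `Nb * Nc^2 * titer`, available directly as `mode = "simplified"`.
#'
#' @param stats a `bucket_stats` object (from [bucket_stats()] or a
#'   [sampen_ba()] result).
#' @param costs a [cycle_costs()] object.
#' @param mode `"full"` (default) or `"simplified"`.
#' @param nc_stat which occupancy statistic stands in for `Nc`: `"mean"`
#'   (default, approximates total work) or `"max"` (worst case).
#' @param nnw optional neighbour-window override; defaults to the `2m + 1`
#'   recorded in `stats`.
#' @return A `latency_estimate`.
#' @examples
#' st <- structure(list(nb = 10, nc_max = 4, nc_mean = 4, nnw = 5),
#'                 class = "bucket_stats")
#' estimate_ba_latency(st, cycle_costs(titer = 3), mode = "simplified")
#' @export
estimate_ba_latency <- function(stats, costs = cycle_costs(),
                                mode = c("full", "simplified"),
                                nc_stat = c("mean", "max"), nnw = NULL) {
  mode <- match.arg(mode)
  nc_stat <- match.arg(nc_stat)
  stopifnot(inherits(stats, "bucket_stats"), inherits(costs, "cycle_costs"))
  nc <- if (nc_stat == "mean") stats$nc_mean else stats$nc_max
  nnw <- if (is.null(nnw)) stats$nnw else nnw
  stopifnot(nnw >= 0)
  if (mode == "simplified") {
    breakdown <- list(search = stats$nb * nc * nc * costs$titer)
    details <- list(nb = stats$nb, nc = nc, nc_stat = nc_stat)
  } else {
    t1 <- costs$titer * nc + costs$r1_corr
    t2 <- t1 * nc + costs$r2_corr
    t3 <- t2 * nnw + costs$r3_corr
    breakdown <- list(search = stats$nb * t3, init = costs$Ti,
                      assign = costs$Ta)
    details <- list(t1 = t1, t2 = t2, t3 = t3, nb = stats$nb, nc = nc,
                    nnw = nnw, nc_stat = nc_stat)
  }
  new_latency_estimate(breakdown, details, costs$freq, paste0("ba_", mode))
}

#' BubbleSort latency estimate
#'
#' `t1 = tcomparison * sum(1..N)` (the comparison term as published),
#' `t2 = texchange * exchanges` with the exchange count measured from an
#' actual sort of the input, `t3 = bs_r2 * (N - 1)`.
#'
#' @param n series length.
#' @param stats a `sort_stats` object from a BubbleSort run on the same
#'   input ([sort_indexed()] with `algorithm = "bubble"`).
#' @param costs a [cycle_costs()] object.
#' @return A `latency_estimate`.
#' @export
estimate_bs_latency <- function(n, stats, costs = cycle_costs()) {
  stopifnot(inherits(costs, "cycle_costs"), n >= 1)
  if (!inherits(stats, "sort_stats") || !is.finite(stats$exchanges)) {
    stop("missing exchange count: `stats` must come from a bubble sort")
  }
  t1 <- costs$tcomparison * n * (n + 1) / 2
  t2 <- costs$texchange * stats$exchanges
  t3 <- costs$bs_r2 * (n - 1)
  new_latency_estimate(list(comparison = t1, exchange = t2, per_iteration = t3),
                       list(exchanges = stats$exchanges), costs$freq, "bs")
}

#' MergeSort latency estimate
#'
#' `Ml = ceil(log2 N)` merge layers; `t1 = tm * N * Ml` element merges,
#' `t2 = ts * sum over layers of ceil(N / 2^layer)` subsequence merges,
#' `t3 = tl * Ml` layer overhead.  A single-element series needs no merging.
#'
#' @param n series length.
#' @param costs a [cycle_costs()] object.
#' @return A `latency_estimate`; `$details` carries the per-layer widths and
#'   subsequence counts.
#' @examples
#' estimate_ms_latency(8, cycle_costs(tm = 1, ts = 0, tl = 0))
#' @export
estimate_ms_latency <- function(n, costs = cycle_costs()) {
  stopifnot(inherits(costs, "cycle_costs"), n >= 1)
  ml <- if (n <= 1) 0L else as.integer(ceiling(log2(n)))
  nm <- seq_len(ml)
  mi <- if (ml > 0) ceiling(n / 2^nm) else numeric(0)
  t1 <- costs$tm * n * ml
  t2 <- costs$ts * sum(mi)
  t3 <- costs$tl * ml
  new_latency_estimate(list(merge = t1, subsequence = t2, layer = t3),
                       list(layers = ml, widths = 2^nm, subsequences = mi),
                       costs$freq, "ms")
}

#' Lightweight similarity-search latency estimate
#'
#' `T = (tc * Nn + c1) * N + c2 * N` plus the cycles of the chosen sorting
#' stage.
#'
#' @param n series length.
#' @param nn_mean mean sorted-neighbour count within tolerance (see
#'   [extract_nn()]).
#' @param sort_estimate a `latency_estimate` for the sorting stage
#'   ([estimate_bs_latency()] or [estimate_ms_latency()]), or `NULL` for the
#'   search stage alone.
#' @param costs a [cycle_costs()] object.
#' @return A `latency_estimate`.
#' @export
estimate_lw_latency <- function(n, nn_mean, sort_estimate = NULL,
                                costs = cycle_costs()) {
  stopifnot(inherits(costs, "cycle_costs"), n >= 1, nn_mean >= 0)
  sort_cycles <- 0
  if (!is.null(sort_estimate)) {
    stopifnot(inherits(sort_estimate, "latency_estimate"))
    sort_cycles <- sort_estimate$cycles
  }
  search <- (costs$tc * nn_mean + costs$c1) * n + costs$c2 * n
  new_latency_estimate(list(search = search, sort = sort_cycles),
                       list(nn_mean = nn_mean), costs$freq, "lw")
}

#' Latency estimates for a design-parameter sweep
#'
#' Applies the latency models row-wise to the output of
#' [sweep_design_params()]: the bucket-assisted full chain from `Nb` and
#' `Nc_mean`, MergeSort-lightweight from `N` and the mean `Nn`, and
#' BubbleSort-lightweight when exchange counts are present.
#'
#' @param design a data frame with columns `n`, `nb`, `nc_mean` and
#'   optionally `nn_mean`, `exchanges`.
#' @param costs a [cycle_costs()] object.
#' @param m embedding dimension used in the sweep (sets the neighbour
#'   window `2m + 1`).
#' @return `design` with added cycle/second columns per estimable algorithm.
#' @export
estimate_latency_table <- function(design, costs = cycle_costs(), m = 2L) {
  stopifnot(is.data.frame(design),
            all(c("n", "nb", "nc_mean") %in% names(design)))
  out <- design
  n_rows <- nrow(design)
  ba <- vapply(seq_len(n_rows), function(i) {
    st <- structure(list(nb = design$nb[i], nc_max = design$nc_max[i],
                         nc_mean = design$nc_mean[i], nnw = 2L * m + 1L),
                    class = "bucket_stats")
    estimate_ba_latency(st, costs)$cycles
  }, numeric(1))
  out$ba_cycles <- ba
  out$ba_seconds <- ba / costs$freq
  if ("nn_mean" %in% names(design) && any(is.finite(design$nn_mean))) {
    ms <- vapply(seq_len(n_rows), function(i) {
      if (!is.finite(design$nn_mean[i])) return(NA_real_)
      estimate_lw_latency(design$n[i], design$nn_mean[i],
                          estimate_ms_latency(design$n[i], costs), costs)$cycles
    }, numeric(1))
    out$ms_lw_cycles <- ms
    out$ms_lw_seconds <- ms / costs$freq
  }
  if ("exchanges" %in% names(design) && any(is.finite(design$exchanges))) {
    bs <- vapply(seq_len(n_rows), function(i) {
      if (!is.finite(design$exchanges[i]) || !is.finite(design$nn_mean[i])) {
        return(NA_real_)
      }
      st <- structure(list(algorithm = "bubble", comparisons = NA_real_,
                           exchanges = design$exchanges[i],
                           merge_ops = NA_real_, layers = NA_integer_),
                      class = "sort_stats")
      estimate_lw_latency(design$n[i], design$nn_mean[i],
                          estimate_bs_latency(design$n[i], st, costs),
                          costs)$cycles
    }, numeric(1))
    out$bs_lw_cycles <- bs
    out$bs_lw_seconds <- bs / costs$freq
  }
  out
}
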