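# Equivalence suites, execution-time benchmarks and design-parameter sweeps
# over grids of generated inputs.  These functions back the command-line
# front end (inst/cli/fastsampen-cli.R).

#' Sweep configuration
#'
#' Defines the grid of generated inputs for [run_equivalence_suite()],
#' [run_benchmark()] and [sweep_design_params()].  The default grid brackets
#' lengths 10-20,000 and SNR 5-100 dB.
#'
#' @param lengths series lengths N.
#' @param snr_db signal-to-noise ratios in dB (noisy-sine cells).
#' @param seeds_per_cell independent replicates per grid cell.
#' @param algorithms subset of `c("sf", "ba", "bs_lw", "ms_lw")`.
#' @param params a [sampen_params()] object.
#' @param repetitions timing repeats for [run_benchmark()].
#' @param signals input families: any of `"sine"`, `"ecg"`, `"uniform"`.
#' @param base_seed integer from which per-cell seeds are derived
#'   deterministically.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(lengths = c(10, 50, 100, 500, 2000, 20000),
                         snr_db = c(5, 10, 20, 50, 100),
                         seeds_per_cell = 5,
                         algorithms = c("sf", "ba", "bs_lw", "ms_lw"),
                         params = sampen_params(),
                         repetitions = 3,
                         signals = "sine",
                         base_seed = 1L) {
  stopifnot(length(lengths) >= 1, all(lengths >= 1),
            length(snr_db) >= 1, seeds_per_cell >= 1, repetitions >= 1,
            inherits(params, "sampen_params"))
  algorithms <- match.arg(algorithms, c("sf", "ba", "bs_lw", "ms_lw"),
                          several.ok = TRUE)
  signals <- match.arg(signals, c("sine", "ecg", "uniform"),
                       several.ok = TRUE)
  structure(list(lengths = as.integer(lengths), snr_db = as.numeric(snr_db),
                 seeds_per_cell = as.integer(seeds_per_cell),
                 algorithms = algorithms, params = params,
                 repetitions = as.integer(repetitions), signals = signals,
                 base_seed = as.integer(base_seed)),
            class = "sweep_config")
}

# Enumerate the input cells of a config as a data frame.  snr_db is NA for
# the ecg/uniform families (it only parameterizes the sine cells).  Seeds
# are deterministic in (base_seed, cell order, replicate).
sweep_cells <- function(config) {
  cells <- list()
  for (sig in config$signals) {
    snrs <- if (sig == "sine") config$snr_db else NA_real_
    cells[[sig]] <- expand.grid(signal = sig, n = config$lengths,
                                snr_db = snrs,
                                replicate = seq_len(config$seeds_per_cell),
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out$seed <- config$base_seed + 1000L * (seq_len(nrow(out)) - 1L) +
    (out$replicate - 1L)
  out
}

generate_cell <- function(cell) {
  n <- cell$n
  switch(cell$signal,
         sine = generate_noisy_sine(n, snr_db = cell$snr_db, seed = cell$seed),
         ecg = generate_ecg_like(n, beat_period = max(10L, min(250L, n %/% 4L)),
                                 noise_sd = 0.1, seed = cell$seed),
         uniform = with_seed(cell$seed, stats::runif(n)))
}

run_algorithm <- function(x, params, algorithm) {
  switch(algorithm,
         sf = sampen_sf(x, params),
         ba = sampen_ba(x, params),
         bs_lw = sampen_lw(x, params, "bubble"),
         ms_lw = sampen_lw(x, params, "merge"))
}

#' Cross-algorithm equivalence suite
#'
#' Runs every selected algorithm on every generated input and checks that
#' the match counts are bit-identical to the straightforward reference and
#' that the entropy agrees within `tol` (with undefined results matching
#' exactly).  This operationalizes the headline correctness property of the
#' accelerated algorithms.
#'
#' @param config a [sweep_config()].
#' @param tol entropy agreement tolerance for defined results.
#' @return A data frame with one row per (input cell, algorithm) and logical
#'   columns `counts_equal`, `value_equal`, `pass`; the attribute
#'   `"all_pass"` summarizes it.
#' @export
run_equivalence_suite <- function(config = sweep_config(), tol = 1e-12) {
  stopifnot(inherits(config, "sweep_config"))
  cells <- sweep_cells(config)
  algos <- setdiff(config$algorithms, "sf")
  rows <- vector("list", nrow(cells) * max(1L, length(algos)))
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    x <- generate_cell(cell)
    ref <- sampen_sf(x, config$params)
    for (alg in algos) {
      res <- run_algorithm(x, config$params, alg)
      counts_equal <- identical(res$count1, ref$count1) &&
        identical(res$count2, ref$count2)
      value_equal <- if (ref$defined && res$defined) {
        abs(res$value - ref$value) <= tol
      } else {
        identical(res$defined, ref$defined)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(signal = cell$signal, n = cell$n,
                              snr_db = cell$snr_db, seed = cell$seed,
                              algorithm = alg,
                              counts_equal = counts_equal,
                              value_equal = value_equal,
                              pass = counts_equal && value_equal)
    }
  }
  report <- do.call(rbind, rows[seq_len(k)])
  rownames(report) <- NULL
  attr(report, "all_pass") <- all(report$pass)
  report
}

#' Execution-time and work-counter benchmark
#'
#' Times every selected algorithm on every generated input (median wall
#' clock over `repetitions`) and records the element-comparison counters of
#' the matching phase.  Timing numbers are reported, never asserted; the
#' comparison counters are the machine-independent complexity measure.
#'
#' @param config a [sweep_config()].
#' @return A data frame with columns `algorithm`, `signal`, `n`, `snr_db`,
#'   `seed`, `median_seconds`, `comparisons_performed`, `sampen`.
#' @export
run_benchmark <- function(config = sweep_config()) {
  stopifnot(inherits(config, "sweep_config"))
  cells <- sweep_cells(config)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    x <- generate_cell(cell)
    for (alg in config$algorithms) {
      times <- numeric(config$repetitions)
      res <- NULL
      for (rep in seq_len(config$repetitions)) {
        t0 <- proc.time()[["elapsed"]]
        res <- run_algorithm(x, config$params, alg)
        times[rep] <- proc.time()[["elapsed"]] - t0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, signal = cell$signal, n = cell$n,
        snr_db = cell$snr_db, seed = cell$seed,
        median_seconds = stats::median(times),
        comparisons_performed = res$comparisons,
        sampen = res$value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Design-parameter sweep
#'
#' Extracts, per generated input, the statistics that size a hardware
#' implementation: bucket count `Nb`, occupancies `Nc_max`/`Nc_mean`, the
#' mean sorted-neighbour count `Nn`, and (optionally) BubbleSort exchange
#' counts.  Bucket construction is linear in N, so the sweep is cheap even
#' at N = 20,000.
#'
#' @param config a [sweep_config()].
#' @param sort_algorithm `"merge"` (default; gives `nn_mean`), `"bubble"`
#'   (additionally gives exchange counts, at quadratic cost), or `"none"`
#'   (bucket statistics only).
#' @return A data frame with columns `signal`, `n`, `snr_db`, `seed`, `nb`,
#'   `nc_max`, `nc_mean`, `nn_mean`, `exchanges`.
#' @export
sweep_design_params <- function(config = sweep_config(),
                                sort_algorithm = c("merge", "bubble", "none")) {
  stopifnot(inherits(config, "sweep_config"))
  sort_algorithm <- match.arg(sort_algorithm)
  cells <- sweep_cells(config)
  params <- config$params
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    x <- generate_cell(cell)
    prep <- prepare_series(x, params)
    sums <- template_sums(prep$x, params$m)
    table <- build_buckets(sums, prep$r_eff)
    st <- bucket_stats(table, params$m)
    nn_mean <- NA_real_
    exchanges <- NA_real_
    if (sort_algorithm != "none") {
      sorted <- sort_indexed(prep$x, sort_algorithm)
      nn_mean <- extract_nn(sorted, prep$r_eff)
      if (sort_algorithm == "bubble") exchanges <- sorted$stats$exchanges
    }
    rows[[ci]] <- data.frame(signal = cell$signal, n = cell$n,
                             snr_db = cell$snr_db, seed = cell$seed,
                             nb = st$nb, nc_max = st$nc_max,
                             nc_mean = st$nc_mean, nn_mean = nn_mean,
                             exchanges = exchanges)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
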