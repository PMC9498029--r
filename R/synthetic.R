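# Synthetic input families: noisy sinusoids over an SNR grid and ECG-like
# quasi-periodic spike trains, plus plain-text readers/writers so every other
# module is testable without external data.

#' Noisy sinusoid generator
#'
#' `amplitude * sin(2*pi*i/samples_per_cycle)` plus i.i.d. Gaussian noise
#' whose SD realizes the requested signal-to-noise ratio:
#' `sd = (amplitude/sqrt(2)) / 10^(snr_db/20)`, i.e. SNR is the power ratio
#' in dB against the sine's RMS.  `snr_db = Inf` disables the noise.
#' Deterministic under a fixed `seed`; the caller's RNG stream is left
#' untouched.
#'
#' @param n number of samples (>= 1).
#' @param samples_per_cycle sampling density (>= 2); the default of 50 gives
#'   the strong adjacent-sample correlation typical of oversampled
#'   physiological waveforms.
#' @param amplitude sine amplitude (> 0).
#' @param snr_db signal-to-noise ratio in dB (may be `Inf`).
#' @param seed integer RNG seed, or `NULL` to use the current stream.
#' @param components if `TRUE`, return `list(values, signal, noise)` so the
#'   realized SNR can be recomputed.
#' @return Numeric series of length `n` (or the component list).
#' @examples
#' x <- generate_noisy_sine(1000, snr_db = 20, seed = 1)
#' @export
generate_noisy_sine <- function(n, samples_per_cycle = 50, amplitude = 1,
                                snr_db = 20, seed = NULL,
                                components = FALSE) {
  stopifnot(n >= 1, n == as.integer(n), samples_per_cycle >= 2,
            amplitude > 0, is.numeric(snr_db), length(snr_db) == 1L,
            !is.na(snr_db))
  signal <- amplitude * sin(2 * pi * (seq_len(n) - 1) / samples_per_cycle)
  noise_sd <- if (is.infinite(snr_db)) 0 else
    (amplitude / sqrt(2)) / 10^(snr_db / 20)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n, mean = 0, sd = noise_sd))
  } else {
    numeric(n)
  }
  if (components) list(values = signal + noise, signal = signal, noise = noise)
  else signal + noise
}

#' ECG-like quasi-periodic signal generator
#'
#' A stand-in for real electrocardiogram records: a periodic train of sharp
#' Gaussian-shaped spikes (QRS-like), a slow baseline oscillation
#' (respiration-like, period `5 * beat_period`), and additive Gaussian
#' noise.  With `noise_sd = 0` and `baseline_amplitude = 0` the signal is
#' exactly periodic.  Deterministic under a fixed `seed`.
#'
#' @param n number of samples (>= 1).
#' @param beat_period samples per beat (>= 2).
#' @param spike_amplitude height of the spike component.
#' @param baseline_amplitude amplitude of the slow baseline oscillation.
#' @param noise_sd SD of the additive Gaussian noise.
#' @param seed integer RNG seed, or `NULL`.
#' @return Numeric series of length `n`.
#' @examples
#' x <- generate_ecg_like(2000, beat_period = 250, seed = 3)
#' @export
generate_ecg_like <- function(n, beat_period = 250, spike_amplitude = 1,
                              baseline_amplitude = 0.1, noise_sd = 0.05,
                              seed = NULL) {
  stopifnot(n >= 1, n == as.integer(n), beat_period >= 2,
            spike_amplitude >= 0, baseline_amplitude >= 0, noise_sd >= 0)
  t <- seq_len(n) - 1
  phase <- (t %% beat_period) - beat_period / 2
  width <- beat_period / 25
  spikes <- spike_amplitude * exp(-0.5 * (phase / width)^2)
  baseline <- baseline_amplitude * sin(2 * pi * t / (5 * beat_period))
  noise <- if (noise_sd > 0) with_seed(seed, stats::rnorm(n, 0, noise_sd))
           else numeric(n)
  spikes + baseline + noise
}

#' Read a 1-D series from a text file
#'
#' Plain format: one numeric value per row (blank lines ignored); parse
#' failures are reported with their line numbers.  CSV format: a named
#' numeric column.
#'
#' @param path file path.
#' @param format `"plain"` (default) or `"csv"`.
#' @param column column name for CSV input; defaults to the only column if
#'   the file has exactly one.
#' @return Numeric vector in file order.
#' @export
read_series <- function(path, format = c("plain", "csv"), column = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "plain") {
    lines <- readLines(path)
    keep <- nzchar(trimws(lines))
    if (!any(keep)) stop(sprintf("empty input: %s", path))
    vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
    bad <- which(is.na(vals))
    if (length(bad)) {
      lineno <- which(keep)[bad]
      stop(sprintf("non-numeric rows in %s at line(s): %s", path,
                   paste(utils::head(lineno, 5), collapse = ", ")))
    }
    vals
  } else {
    df <- utils::read.csv(path)
    if (nrow(df) == 0) stop(sprintf("empty input: %s", path))
    if (is.null(column)) {
      if (ncol(df) != 1L) {
        stop("`column` must name the series column for multi-column CSV input")
      }
      column <- names(df)[1]
    }
    if (!column %in% names(df)) {
      stop(sprintf("column `%s` not found in %s", column, path))
    }
    v <- df[[column]]
    if (!is.numeric(v)) {
      stop(sprintf("column `%s` in %s is not numeric", column, path))
    }
    as.numeric(v)
  }
}

#' Write a 1-D series to a text file
#'
#' Inverse of [read_series()]; a written series reads back identically
#' (values are printed at full precision).
#'
#' @param x numeric series.
#' @param path output file path.
#' @param format `"plain"` (default) or `"csv"`.
#' @param column column name used for CSV output.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path, format = c("plain", "csv"),
                         column = "value") {
  format <- match.arg(format)
  x <- check_series(x)
  txt <- formatC(x, digits = 17, format = "g")
  if (format == "plain") {
    writeLines(txt, path)
  } else {
    df <- data.frame(v = txt)
    names(df) <- column
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
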