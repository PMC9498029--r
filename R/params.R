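#' Sample entropy parameters
#'
#' Bundles the embedding dimension `m`, the tolerance `r` and how `r` is to
#' be interpreted.  With `r_mode = "relative_to_sd"` (the literature
#' convention behind the usual r = 0.15) the input series is z-normalized
#' internally and the tolerance is `r` times its sample standard deviation;
#' with `"absolute"` the series is used as-is and `r` is in signal units.
#'
#' @param m embedding dimension (template length at the base scale), a
#'   positive integer.  Default 2.
#' @param r tolerance, a positive real.  Default 0.15.
#' @param r_mode `"relative_to_sd"` (default) or `"absolute"`.
#' @return An object of class `sampen_params`.
#' @examples
#' sampen_params()                 # m = 2, r = 0.15 relative to SD
#' sampen_params(3, 0.2, "absolute")
#' @export
sampen_params <- function(m = 2L, r = 0.15,
                          r_mode = c("relative_to_sd", "absolute")) {
  r_mode <- match.arg(r_mode)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 1 ||
      m != as.integer(m)) {
    stop("`m` must be a positive integer")
  }
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("`r` must be a positive finite number")
  }
  structure(list(m = as.integer(m), r = as.numeric(r), r_mode = r_mode),
            class = "sampen_params")
}

#' @export
print.sampen_params <- function(x, ...) {
  cat(sprintf("SampEn parameters: m = %d, r = %g (%s)\n",
              x$m, x$r, x$r_mode))
  invisible(x)
}

# Validate a raw input series.
check_series <- function(x, min_len = 1L, name = "x") {
  if (!is.numeric(x)) stop(sprintf("`%s` must be a numeric vector", name))
  x <- as.numeric(x)
  if (length(x) < min_len) {
    stop(sprintf("`%s` must have at least %d samples (got %d)",
                 name, min_len, length(x)))
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name))
  }
  x
}

#' Z-normalize a time series
#'
#' Centers to mean 0 and scales to sample standard deviation 1.  Used
#' internally when the tolerance is interpreted relative to the SD, so that
#' SampEn is invariant under affine transforms of the input.
#'
#' @param x numeric series with at least two samples and nonzero variance.
#' @return Numeric series of the same length, mean 0, sample SD 1.
#' @examples
#' normalize_series(c(-1, 1))
#' @export
normalize_series <- function(x) {
  name <- deparse1(substitute(x))
  x <- check_series(x, min_len = 2L, name = name)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) {
    stop(sprintf("degenerate input: series `%s` has zero variance", name))
  }
  (x - mean(x)) / s
}

#' Effective matching tolerance
#'
#' Resolves a [sampen_params()] tolerance against a concrete series: `r`
#' itself in absolute mode, `r` times the sample SD of `x` in relative mode.
#'
#' @param x numeric series.
#' @param params a [sampen_params()] object.
#' @return The effective tolerance (positive real, signal units).
#' @export
effective_tolerance <- function(x, params) {
  stopifnot(inherits(params, "sampen_params"))
  if (params$r_mode == "absolute") return(params$r)
  x <- check_series(x, min_len = 2L)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate input: zero-variance series in relative tolerance mode")
  }
  params$r * s
}

# Resolve (x, params) into the series actually matched and the tolerance in
# its units.  Relative mode z-normalizes, after which the effective tolerance
# is r itself; this is what makes the bucket statistics comparable across
# inputs of different scales.
prepare_series <- function(x, params) {
  stopifnot(inherits(params, "sampen_params"))
  x <- check_series(x, min_len = 2L)
  if (params$r_mode == "relative_to_sd") {
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) {
      stop("degenerate input: zero-variance series in relative tolerance mode")
    }
    list(x = (x - mean(x)) / s, r_eff = params$r)
  } else {
    list(x = x, r_eff = params$r)
  }
}
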