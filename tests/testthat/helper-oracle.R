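# Definition-level reference implementation, kept deliberately independent of
# the package internals: templates are materialized, every ordered pair is
# enumerated, and the Chebyshev distance is evaluated in full.  Used as the
# ground truth the fast implementations must reproduce.

oracle_counts <- function(x, m, r) {
  n <- length(x)
  templ <- function(i, scale) x[i:(i + scale - 1)]
  count_at_scale <- function(scale) {
    n_templates <- n - scale + 1
    count <- 0
    for (i in seq_len(n_templates)) {
      for (j in seq_len(n_templates)) {
        if (i != j && max(abs(templ(i, scale) - templ(j, scale))) <= r) {
          count <- count + 1
        }
      }
    }
    count
  }
  list(count1 = count_at_scale(m), count2 = count_at_scale(m + 1))
}

oracle_sampen <- function(x, m, r) {
  n <- length(x)
  cnt <- oracle_counts(x, m, r)
  B <- cnt$count1 / ((n - m + 1) * (n - m))
  A <- cnt$count2 / ((n - m) * (n - m - 1))
  if (A == 0) list(value = NA_real_, defined = FALSE, A = A, B = B)
  else list(value = -log(A / B), defined = TRUE, A = A, B = B)
}

# Matching-phase preparation mirroring the package default (z-normalize,
# tolerance r in SD units), written out longhand.
oracle_prepare <- function(x, r) {
  z <- (x - mean(x)) / sd(x)
  list(x = z, r_eff = r)
}

# Small random test series with a mix of characters.
random_series <- function(n, seed, kind = c("gauss", "sine", "ecg", "uniform")) {
  kind <- match.arg(kind)
  switch(kind,
         gauss = {set.seed(seed); rnorm(n)},
         sine = generate_noisy_sine(n, snr_db = 15, seed = seed),
         ecg = generate_ecg_like(n, beat_period = max(10, n %/% 5),
                                 seed = seed),
         uniform = {set.seed(seed); runif(n)})
}
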