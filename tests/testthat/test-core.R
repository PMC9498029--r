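test_that("normalize_series centers and scales; degenerate input errors", {
  z <- normalize_series(c(-1, 1))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(z[1], -z[2])

  expect_error(normalize_series(c(5, 5, 5, 5)), "zero variance")

  set.seed(11)
  g <- rnorm(1000, mean = 3, sd = 7)
  zg <- normalize_series(g)
  expect_lt(abs(mean(zg)), 1e-12)
  expect_lt(abs(sd(zg) - 1), 1e-12)
  expect_equal(length(zg), 1000L)
})

test_that("effective tolerance follows the r interpretation mode", {
  x_unit <- c(-1.5, -0.5, 0.5, 1.5) / sd(c(-1.5, -0.5, 0.5, 1.5))  # SD 1
  expect_equal(effective_tolerance(x_unit, sampen_params(r = 0.15)), 0.15)
  expect_equal(effective_tolerance(rnorm(10), sampen_params(r = 0.15, r_mode = "absolute")),
               0.15)
  x2 <- c(0, 2, 4, 6) / sd(c(0, 2, 4, 6)) * 2  # SD 2
  expect_equal(effective_tolerance(x2, sampen_params(r = 0.2)), 0.4)
  expect_error(effective_tolerance(rep(1, 5), sampen_params()), "zero")
})

test_that("template matching uses the inclusive Chebyshev criterion", {
  x <- c(1.0, 1.1, 2.0, 1.05, 1.12)
  expect_true(template_match(x, 1, 1, 3, 1e-9))      # self-distance 0
  expect_false(template_match(c(0, 10, 0, 10), 1, 2, 2, 1))
  # max(|1.0-1.05|, |1.1-1.12|) = 0.05 <= 0.15
  expect_true(template_match(x, 1, 4, 2, 0.15))
  # boundary: distance exactly r matches (non-strict)
  expect_true(template_match(c(0, 1, 0.15, 1.15), 1, 3, 2, 0.15))
  expect_error(template_match(x, 1, 5, 2, 0.1), "out of range")
})

test_that("straightforward counts match hand-computable cases", {
  cnt <- sf_counts(rep(5, 5), 2, 0.3)
  expect_equal(cnt$count1, 12)  # 4 templates, all ordered non-self pairs
  expect_equal(cnt$count2, 6)   # 3 templates at scale m+1
  expect_true(cnt$self_corrected)

  cnt0 <- sf_counts(c(0, 10, 20, 30, 40), 2, 1)
  expect_equal(cnt0$count1, 0)
  expect_equal(cnt0$count2, 0)

  expect_error(sf_counts(c(1, 2, 3), 2, 0.1), "too short")
})

test_that("straightforward counts equal the definition-level enumeration", {
  cases <- expand.grid(n = c(12, 30, 50), kind = c("gauss", "sine", "uniform"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    x <- random_series(cases$n[i], seed = 100 + i, kind = cases$kind[i])
    prep <- oracle_prepare(x, 0.15)
    expected <- oracle_counts(prep$x, 2, prep$r_eff)
    got <- sf_counts(prep$x, 2, prep$r_eff)
    expect_equal(got$count1, expected$count1)
    expect_equal(got$count2, expected$count2)
  }
  # and for a different embedding dimension
  x <- random_series(40, seed = 7, kind = "gauss")
  expected <- oracle_counts(x, 3, 0.4)
  got <- sf_counts(x, 3, 0.4)
  expect_equal(got$count1, expected$count1)
  expect_equal(got$count2, expected$count2)
})

test_that("counts convert to entropy via the printed denominators", {
  res <- entropy_from_counts(sf_counts(rep(5, 5), 2, 0.3), n = 5, m = 2)
  expect_equal(res$B, 1)
  expect_equal(res$A, 1)
  expect_equal(res$value, 0)
  expect_true(res$defined)

  res0 <- entropy_from_counts(sf_counts(c(0, 10, 20, 30, 40), 2, 1), n = 5, m = 2)
  expect_false(res0$defined)
  expect_true(is.na(res0$value))
  expect_match(res0$reason, "no m\\+1-scale match")

  cnt <- structure(list(count1 = 20, count2 = 5, self_corrected = TRUE,
                        comparisons = NA_real_), class = "match_counts")
  res2 <- entropy_from_counts(cnt, n = 12, m = 2)
  expect_equal(res2$B, 20 / 110)
  expect_equal(res2$A, 5 / 90)
  expect_equal(res2$value, -log((5 / 90) / (20 / 110)))

  raw <- structure(list(count1 = 20, count2 = 5, self_corrected = FALSE),
                   class = "match_counts")
  expect_error(entropy_from_counts(raw, 12, 2), "self-corrected")
})

test_that("sampen_sf equals the definition-level oracle end to end", {
  x <- generate_noisy_sine(200, snr_db = 10, seed = 5)
  prep <- oracle_prepare(x, 0.15)
  expected <- oracle_sampen(prep$x, 2, prep$r_eff)
  got <- sampen_sf(x)
  expect_true(got$defined == expected$defined)
  expect_equal(got$value, expected$value, tolerance = 1e-12)
  expect_equal(got$A, expected$A)
  expect_equal(got$B, expected$B)
})

test_that("probabilities are bounded and entropy non-negative on random inputs", {
  for (s in 1:20) {
    n <- 10 + 17 * s
    x <- random_series(n, seed = s,
                       kind = c("gauss", "sine", "uniform")[1 + s %% 3])
    res <- sampen_sf(x)
    expect_lte(res$count2, res$count1)
    expect_gte(res$B, 0); expect_lte(res$B, 1)
    expect_gte(res$A, 0); expect_lte(res$A, 1)
    if (res$defined) expect_gte(res$value, 0)
  }
})

test_that("relative mode is invariant under affine transforms of the input", {
  for (s in 1:8) {
    x <- random_series(120, seed = 40 + s, kind = "sine")
    a <- c(2, -3, 0.5, 10)[1 + s %% 4]
    b <- c(0, 1, -7, 100)[1 + s %% 4]
    r1 <- sampen_sf(x)
    r2 <- sampen_sf(a * x + b)
    expect_equal(r2$count1, r1$count1)
    expect_equal(r2$count2, r1$count2)
    expect_equal(r2$value, r1$value)
  }
})

test_that("constant series yields zero entropy for all valid lengths", {
  p <- sampen_params(r_mode = "absolute")
  for (n in 4:12) {
    res <- sampen_sf(rep(3.7, n), p)
    expect_equal(res$value, 0)
    expect_equal(res$count1, (n - 1) * (n - 2))
    expect_equal(res$count2, (n - 2) * (n - 3))
  }
})
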