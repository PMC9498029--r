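make_bucket_stats <- function(nb, nc, nnw = 5) {
  structure(list(nb = nb, nc_max = nc, nc_mean = nc, nnw = nnw),
            class = "bucket_stats")
}

test_that("bucket-assisted latency follows the printed chain", {
  st <- make_bucket_stats(nb = 10, nc = 4)
  costs <- cycle_costs(titer = 3)
  expect_equal(estimate_ba_latency(st, costs, mode = "simplified")$cycles,
               10 * 4 * 4 * 3)  # Nb * Nc * Nc * titer = 480
  full <- estimate_ba_latency(st, costs, mode = "full", nnw = 5)
  expect_equal(full$cycles, 10 * (3 * 4 * 4 * 5))  # 2400
  expect_equal(full$details$t1, 12)
  expect_equal(full$details$t2, 48)
  expect_equal(full$details$t3, 240)

  # cycles-to-seconds conversion at 100 MHz
  expect_equal(estimate_ba_latency(make_bucket_stats(1, 1),
                                   cycle_costs(titer = 1e6, freq = 100e6),
                                   mode = "simplified")$seconds, 0.01)

  expect_error(cycle_costs(titer = -1), "non-negative")
})

test_that("full chain with unit window and zero corrections equals the simplified product", {
  set.seed(5)
  for (k in 1:25) {
    st <- make_bucket_stats(nb = sample(1:200, 1), nc = runif(1, 0.5, 50))
    costs <- cycle_costs(titer = runif(1, 0.5, 10))
    full1 <- estimate_ba_latency(st, costs, mode = "full", nnw = 1)
    simp <- estimate_ba_latency(st, costs, mode = "simplified")
    expect_equal(full1$cycles, simp$cycles)
    # and in general the full chain is the simplified product times Nnw
    fullw <- estimate_ba_latency(st, costs, mode = "full", nnw = st$nnw)
    expect_equal(fullw$cycles, simp$cycles * st$nnw)
  }
})

test_that("bubble-sort latency uses the printed comparison sum and measured exchanges", {
  # t1 = tcomparison * sum_{i=1}^{N} i
  st0 <- sort_indexed(c(1, 2, 3, 4), "bubble")$stats
  est <- estimate_bs_latency(4, st0, cycle_costs(tcomparison = 1, texchange = 0))
  expect_equal(est$breakdown$comparison, 10)

  rev4 <- sort_indexed(c(4, 3, 2, 1), "bubble")$stats
  est2 <- estimate_bs_latency(4, rev4, cycle_costs(tcomparison = 0, texchange = 2))
  expect_equal(est2$breakdown$exchange, 12)  # 6 exchanges x 2 cycles

  est3 <- estimate_bs_latency(4, st0, cycle_costs(tcomparison = 1, texchange = 5))
  expect_equal(est3$breakdown$exchange, 0)   # already sorted
  expect_equal(est3$cycles, est3$breakdown$comparison)

  ms_stats <- sort_indexed(c(2, 1), "merge")$stats
  expect_error(estimate_bs_latency(2, ms_stats, cycle_costs()),
               "missing exchange count")
})

test_that("merge-sort latency follows the layer formulas", {
  e1 <- estimate_ms_latency(8, cycle_costs(tm = 1, ts = 0, tl = 0))
  expect_equal(e1$cycles, 24)  # tm * N * Ml = 8 * 3
  e2 <- estimate_ms_latency(8, cycle_costs(tm = 0, ts = 1, tl = 0))
  expect_equal(e2$cycles, 7)   # ceil(8/2)+ceil(8/4)+ceil(8/8) = 4+2+1
  e3 <- estimate_ms_latency(1, cycle_costs())
  expect_equal(e3$cycles, 0)
  expect_equal(e3$details$layers, 0L)
  e5 <- estimate_ms_latency(5, cycle_costs(tm = 0, ts = 1, tl = 0))
  expect_equal(e5$cycles, 3 + 2 + 1)  # ceil(5/2)+ceil(5/4)+ceil(5/8)
})

test_that("lightweight search latency is (tc*Nn + c1)*N + c2*N plus sorting", {
  est <- estimate_lw_latency(100, 3, NULL, cycle_costs(tc = 2, c1 = 0, c2 = 0))
  expect_equal(est$cycles, 600)
  est2 <- estimate_lw_latency(50, 0, NULL, cycle_costs(tc = 2, c1 = 1, c2 = 1))
  expect_equal(est2$cycles, 100)

  # the measured Nn of a constant series feeds the formula
  srt <- sort_indexed(rep(2, 10))
  nn <- extract_nn(srt, 0.3)
  expect_equal(nn, 4.5)
  sort_est <- estimate_ms_latency(10, cycle_costs(tm = 1, ts = 1, tl = 1))
  est3 <- estimate_lw_latency(10, nn, sort_est,
                              cycle_costs(tc = 2, c1 = 1, c2 = 1))
  expect_equal(est3$cycles, (2 * 4.5 + 1) * 10 + 1 * 10 + sort_est$cycles)
})

test_that("latency estimates are non-negative, monotone, and dimensionally consistent", {
  set.seed(9)
  for (k in 1:20) {
    nb <- sample(1:100, 1); nc <- runif(1, 0, 20)
    costs <- cycle_costs(titer = runif(1, 0, 5), Ti = runif(1, 0, 10),
                         Ta = runif(1, 0, 10), r1_corr = runif(1, 0, 2),
                         r2_corr = runif(1, 0, 2), r3_corr = runif(1, 0, 2))
    est <- estimate_ba_latency(make_bucket_stats(nb, nc), costs)
    expect_gte(est$cycles, 0)
    expect_equal(est$seconds * costs$freq, est$cycles)
    # monotone in Nb, Nc and titer
    expect_gte(estimate_ba_latency(make_bucket_stats(nb + 5, nc), costs)$cycles,
               est$cycles)
    expect_gte(estimate_ba_latency(make_bucket_stats(nb, nc + 1), costs)$cycles,
               est$cycles)
    costs2 <- costs; costs2$titer <- costs$titer + 1
    expect_gte(estimate_ba_latency(make_bucket_stats(nb, nc), costs2)$cycles,
               est$cycles)
  }
  n <- 64
  expect_gte(estimate_ms_latency(2 * n, cycle_costs())$cycles,
             estimate_ms_latency(n, cycle_costs())$cycles)
  expect_gte(estimate_lw_latency(n, 4, NULL, cycle_costs())$cycles,
             estimate_lw_latency(n, 3, NULL, cycle_costs())$cycles)
})

test_that("cycle costs round-trip through JSON and reject unknown keys", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  writeLines('{"titer": 3, "tc": 2, "freq": 5e7}', path)
  costs <- read_cycle_costs(path)
  expect_equal(costs$titer, 3)
  expect_equal(costs$tc, 2)
  expect_equal(costs$freq, 5e7)
  expect_equal(costs$tm, 1)  # untouched default

  bad <- tempfile(fileext = ".json")
  on.exit(unlink(bad), add = TRUE)
  writeLines('{"nope": 1}', bad)
  expect_error(read_cycle_costs(bad), "unknown cycle-cost keys")
})
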