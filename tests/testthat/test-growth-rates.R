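# point formula, exponential fits, growth-phase segmentation

test_that("point growth rate implements r = ln(Nt/N0)/t", {
  expect_equal(point_growth_rate(100, 100, 50)$rate, 0)
  expect_equal(point_growth_rate(1, exp(1), 1)$rate, 1)
  expect_equal(point_growth_rate(100, 1e9, log(1e7) / 0.01)$rate, 0.01)
  expect_equal(point_growth_rate(2, 1, 10)$rate, log(0.5) / 10)  # decline
  est <- point_growth_rate(50, 100, 25)
  expect_equal(est$rate_percent, 100 * est$rate)
  expect_equal(annualized_percent(est), 100 * (exp(est$rate) - 1))
  expect_error(point_growth_rate(0, 10, 5), "positive")
  expect_error(point_growth_rate(10, 10, 0), "positive")
})

test_that("time_to_size inverts the point formula (forager paradox numbers)", {
  expect_equal(time_to_size(100, 1e9, 0.01), log(1e7) / 0.01)   # ~1611.8 yr
  expect_equal(time_to_size(100, 1e9, 0.03), log(1e7) / 0.03)   # ~537.3 yr
  expect_equal(time_to_size(100, 100, 0.01), 0)
  expect_error(time_to_size(100, 50, 0.01), "target")
})

test_that("exponential fit is exact on exact exponentials", {
  t <- 0:4000
  expect_equal(fit_exponential(t, exp(0.002 * t))$rate, 0.002, tolerance = 1e-12)
  expect_equal(fit_exponential(t, rep(3.7, length(t)))$rate, 0, tolerance = 1e-12)
  # agreement with the point formula on a 2-parameter exponential
  v <- 5 * exp(-0.0013 * t)
  expect_equal(fit_exponential(t, v)$rate,
               point_growth_rate(v[1], v[length(v)], 4000)$rate, tolerance = 1e-10)
})

test_that("exponential fit: scale invariance, time reversal, zero handling", {
  set.seed(4)
  t <- 0:1500
  v <- exp(0.001 * t) * exp(rnorm(length(t), 0, 0.1))
  r <- fit_exponential(t, v)$rate
  expect_equal(fit_exponential(t, 17.3 * v)$rate, r, tolerance = 1e-12)
  expect_equal(fit_exponential(t, rev(v))$rate, -r, tolerance = 1e-12)
  withz <- v; withz[c(10, 400)] <- 0
  fz <- fit_exponential(t, withz)
  expect_equal(fz$n_excluded, 2L)
  expect_equal(fz$n_points, length(t) - 2L)
  expect_error(fit_exponential(1:5, c(1, 2, 0, 0, 0)), "3 positive")
})

test_that("exponential fit recovers the rate under multiplicative noise", {
  set.seed(11)
  t <- 0:3999
  v <- exp(0.002 * t) * exp(rnorm(4000, 0, 0.1))
  expect_lt(abs(fit_exponential(t, v)$rate - 0.002) / 0.002, 0.05)
})

test_that("fit_exponential methods use forward time on each axis", {
  # size doubling toward the present on a cal BP axis -> positive rate
  bp <- 1000:1
  tr <- population_trajectory(bp, exp(0.001 * (1000 - bp)))
  expect_equal(fit_exponential(tr)$rate, 0.001, tolerance = 1e-10)
  expect_equal(fit_exponential(tr, interval = c(800, 200))$rate, 0.001,
               tolerance = 1e-10)
  spd <- structure(list(cal_bp = 1:1000, prob = exp(-0.002 * 1:1000),
                        n_dates = 1L, normalized = FALSE), class = "spd")
  expect_equal(fit_exponential(spd)$rate, 0.002, tolerance = 1e-10)
  ser <- tax_record_series(1601:1700, round(40 * exp(0.01 * (0:99))))
  expect_equal(fit_exponential(ser)$rate, 0.01, tolerance = 1e-2)
})

test_that("segmentation finds trough-to-peak growth phases", {
  # monotone increasing: one segment covering the whole series
  t <- 0:99
  segs <- segment_growth_rates(t, exp(0.01 * t))
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$interval, c(0, 99))
  expect_equal(segs[[1]]$rate, 0.01, tolerance = 1e-9)
  # constant: empty
  expect_length(segment_growth_rates(t, rep(2, 100)), 0L)
  # sinusoid period 80, mean 100, amplitude 50: rate = ln(3)/40 per phase
  tt <- 0:400
  v <- 100 - 50 * cos(2 * pi * tt / 80)
  segs <- segment_growth_rates(tt, v)
  expect_gte(length(segs), 4L)
  for (s in segs) {
    expect_equal(diff(s$interval), 40)
    expect_equal(s$rate, log(150 / 50) / 40, tolerance = 1e-6)
  }
  # prominence filter ignores small wiggles riding on the cycle
  set.seed(2)
  noisy <- v + rnorm(length(v), 0, 1)
  segs2 <- segment_growth_rates(tt, noisy, prominence = 0.1)
  expect_lte(length(segs2), length(segs) + 1L)
})

test_that("segment methods report intervals on the series' own axis", {
  tr <- default_cycle_trajectory()
  segs <- segment_growth_rates(tr)
  expect_gt(length(segs), 10L)
  for (s in segs[1:3]) expect_gt(s$interval[1], s$interval[2])  # BP decreasing
  rates <- vapply(segs, `[[`, numeric(1), "rate")
  expect_true(all(rates > 0))
})

test_that("fast within-cycle growth vanishes from the whole-range fit", {
  tr <- default_cycle_trajectory()   # stationary cycling series
  whole <- abs(fit_exponential(tr)$rate)
  segs <- segment_growth_rates(tr)
  max_seg <- max(vapply(segs, `[[`, numeric(1), "rate"))
  expect_gte(max_seg, 10 * whole)
})
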