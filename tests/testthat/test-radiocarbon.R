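# calibration curves, calibrate/uncalibrate, date sampling, SPD construction,
# taphonomic correction, forward simulation

test_that("IntCal-dialect files parse, re-sort, and fail with line numbers", {
  f <- withr::local_tempfile(fileext = ".14c")
  write_mini_curve_file(f)
  cv <- read_calibration_curve(f)
  expect_length(cv$cal_bp, 3L)
  expect_identical(cv$cal_bp, c(100, 200, 300))       # ascending after re-sort
  expect_identical(cv$c14_age, c(98, 205, 310))
  bad <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("# hdr", "300,310,8,0,0", "200,205"), bad)
  expect_error(read_calibration_curve(bad), "line 3")
  bad2 <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("300,310,8,0,0", "200,abc,8,0,0"), bad2)
  expect_error(read_calibration_curve(bad2), "line 2")
  # the shipped synthetic fixture is a valid curve
  pkg <- system.file("extdata", "synthetic_calcurve.14c", package = "spdproxy")
  cvs <- read_calibration_curve(pkg)
  expect_gt(length(cvs$cal_bp), 1000L)
  expect_true(all(diff(cvs$cal_bp) > 0))
})

test_that("identity curve is the identity with the requested span", {
  cv <- make_identity_curve(4000, 6000)
  expect_length(cv$cal_bp, 2001L)
  expect_identical(cv$c14_age[cv$cal_bp == 5000], 5000)
  expect_true(all(cv$curve_error == 0))
  expect_error(make_identity_curve(10, 5), "exceed")
})

test_that("calibration of a date on the identity curve is a discretized normal", {
  cv <- make_identity_curve(4000, 6000)
  d <- calibrate(c(5000, 50), cv)
  expect_equal(sum(d$prob), 1, tolerance = 1e-9)
  expect_equal(d$cal_bp[which.max(d$prob)], 5000)
  # central 95.45% mass within +/- 2 sigma (Normal quantiles)
  core <- d$cal_bp >= 4900 & d$cal_bp <= 5100
  expect_equal(sum(d$prob[core]), 2 * pnorm(2) - 1, tolerance = 5e-3)
  # a date far outside the curve underflows everywhere
  expect_error(calibrate(c(20000, 30), cv), "outside")
})

test_that("uncalibration draws truncated-normal errors and tracks the curve", {
  cv <- make_identity_curve(4000, 6000)
  exact <- uncalibrate(c(4500, 5000.5), cv, perturb = FALSE, seed = 1)
  expect_equal(exact$c14_age, c(4500, 5000.5))        # epsilon forced to zero
  sig <- draw_lab_errors(1e5, error_model(), seed = 2)
  expect_true(all(sig >= 20 & sig <= 80))
  expect_lt(abs(mean(sig) - 50), 0.5)                 # symmetric truncation
  expect_error(uncalibrate(9999, cv), "outside")
  # round trip: mode of calibrate(uncalibrate(theta)) is theta, exact to 1 grid yr
  for (theta in c(4250, 4800, 5555)) {
    d <- uncalibrate(theta, cv, perturb = FALSE, seed = 3)
    cal <- calibrate(d, cv)
    expect_equal(cal$cal_bp[which.max(cal$prob)], theta)
  }
})

test_that("calendar-date sampling is weighted by the trajectory", {
  flat <- population_trajectory(2000:1901, rep(5, 100))
  draws <- sample_calendar_dates(flat, 1e5, seed = 1)
  gof <- chisq.test(table(factor(draws, levels = 2000:1901)))
  expect_gt(gof$p.value, 0.01)                        # uniform under flat weights
  spike <- population_trajectory(2000:1901, c(rep(0, 50), 3, rep(0, 49)))
  expect_true(all(sample_calendar_dates(spike, 500, seed = 2) == 1950))
  two <- population_trajectory(2000:1999, c(1, 3))
  d2 <- sample_calendar_dates(two, 4e4, seed = 3)
  frac <- mean(d2 == 1999)
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / 4e4))
  zero <- population_trajectory(2000:1901, rep(0, 100))
  expect_error(sample_calendar_dates(zero, 10), "zero")
})

test_that("SPD is the normalized sum of per-date calibrated densities", {
  cv <- make_identity_curve(4000, 6000)
  dates <- radiocarbon_dates(rep(5000, 7), rep(40, 7))
  spd <- build_spd(dates, cv)
  single <- calibrate(c(5000, 40), cv)
  expect_equal(spd$prob, single$prob, tolerance = 1e-12)  # n identical dates
  expect_equal(sum(spd$prob), 1, tolerance = 1e-9)
  # dual route: build_spd equals the manual average of calibrate() outputs
  mix <- radiocarbon_dates(c(4400, 5200, 5600), c(30, 50, 60))
  spd2 <- build_spd(mix, cv)
  manual <- Reduce(`+`, lapply(seq_len(3), function(i)
    calibrate(mix[i, ], cv)$prob)) / 3
  expect_equal(spd2$prob, manual, tolerance = 1e-12)
  # two well-separated dates give a bimodal SPD with modes at the two ages
  bi <- build_spd(radiocarbon_dates(c(4400, 5600), c(30, 30)), cv)
  near <- function(bp) bi$cal_bp >= bp - 5 & bi$cal_bp <= bp + 5
  expect_equal(bi$cal_bp[which.max(bi$prob * near(4400))], 4400)
  expect_equal(bi$cal_bp[which.max(bi$prob * near(5600))], 5600)
  expect_lt(min(bi$prob[bi$cal_bp > 4800 & bi$cal_bp < 5200]),
            max(bi$prob[near(4400)]) / 100)
  expect_error(build_spd(radiocarbon_dates(numeric(0), numeric(0)), cv), "empty")
})

test_that("taphonomic correction inflates older mass monotonically", {
  cv <- make_identity_curve(2000, 9000)
  uni <- structure(list(cal_bp = 2500:8500, prob = rep(1 / 6001, 6001),
                        n_dates = 1L, normalized = TRUE), class = "spd")
  # constant survival leaves the SPD unchanged after renormalization
  same <- taphonomic_correction(uni, survival = function(t) rep(2, length(t)))
  expect_equal(same$prob, uni$prob, tolerance = 1e-12)
  corr <- taphonomic_correction(uni)
  expect_true(all(diff(corr$prob) > 0))               # strictly increasing with age
  expect_equal(sum(corr$prob), 1, tolerance = 1e-9)
  # fitted growth rate drops when the correction is applied
  grow <- structure(list(cal_bp = 2500:8500,
                         prob = exp(0.0005 * (8500 - 2500:8500)),
                         n_dates = 1L, normalized = FALSE), class = "spd")
  grow$prob <- grow$prob / sum(grow$prob)
  r_before <- fit_exponential(grow)$rate
  r_after <- fit_exponential(taphonomic_correction(grow))$rate
  expect_lt(r_after, r_before)
  expect_error(taphonomic_correction(uni, survival = function(t) t - 5000), "positive")
})

test_that("forward simulation composes the protocol deterministically", {
  tr <- default_cycle_trajectory()
  cv <- make_identity_curve(1, 2600)
  spd <- forward_simulate_spd(tr, 300, c(1900, 100), cv, seed = 77)
  # composition equals the step-by-step pipeline under the same seed
  manual <- local({
    set.seed(77)
    cal <- sample_calendar_dates(tr, 300, c(1900, 100))
    dates <- uncalibrate(cal, cv)
    build_spd(dates, cv)
  })
  expect_equal(spd$prob, manual$prob, tolerance = 1e-12)
  expect_identical(forward_simulate_spd(tr, 300, c(1900, 100), cv, seed = 77)$prob,
                   spd$prob)
  other <- forward_simulate_spd(tr, 300, c(1900, 100), cv, seed = 78)
  expect_gt(max(abs(other$prob - spd$prob)), 0)        # seeds differ -> SPDs differ
})

test_that("SPD smooths the truth toward its long-term trend", {
  # reduced-scale version of the core smoothing property, in the
  # setting it belongs to: a regime shift gives the truth a long-term trend
  params <- dynamics_params()
  tr <- concatenate_regimes(list(productivity_regime(1, 2900, 1301, params),
                                 productivity_regime(2.25, 1300, 1, params)))
  cv <- make_identity_curve(1, 2900)
  spd <- window_spd(forward_simulate_spd(tr, 2000, c(2400, 100), cv, seed = 5),
                    c(2400, 100))
  keep <- tr$years_bp <= 2400 & tr$years_bp >= 100
  truth <- tr$size[keep]
  trend <- spdproxy:::running_mean(truth, 250)        # 500-yr moving average
  spd_fwd <- rev(spd$prob)
  expect_gt(cor(spd_fwd, trend), cor(spd_fwd, truth))
})

test_that("date and SPD CSV round trips preserve values", {
  d <- radiocarbon_dates(c(5000.5, 4400), c(30, 55))
  f <- withr::local_tempfile(fileext = ".csv")
  write_dates_csv(d, f)
  expect_equal(as.data.frame(read_dates_csv(f)), as.data.frame(d))
  cv <- make_identity_curve(4000, 6000)
  spd <- build_spd(d, cv)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_spd_csv(spd, f2)
  back <- read_spd_csv(f2)
  expect_equal(back$prob, spd$prob, tolerance = 1e-12)
  expect_true(back$normalized)
})

test_that("calibrated modes follow the synthetic wiggly curve", {
  # real-curve sanity: a date constructed on the curve calibrates back near theta
  cv <- read_calibration_curve(
    system.file("extdata", "synthetic_calcurve.14c", package = "spdproxy"))
  errs <- vapply(c(5500, 7321, 9800), function(theta) {
    mu <- approx(cv$cal_bp, cv$c14_age, theta)$y
    cal <- calibrate(c(mu, 30), cv)
    abs(cal$cal_bp[which.max(cal$prob)] - theta)
  }, numeric(1))
  expect_lte(stats::median(errs), 30)
})
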