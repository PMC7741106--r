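# consumer-resource simulator, catastrophe model, regime concatenation,
# tax-record observation

test_that("interior equilibrium is a fixed point of the noiseless map", {
  params <- dynamics_params()
  # The fixed point is linearly unstable (that instability is the limit
  # cycle), so double-precision rounding grows like |lambda|^t with
  # |lambda| <= 1.04/yr; 250 years keeps exact-arithmetic invariance
  # verifiable well below the 1e-9 bound.
  for (p in default_productivity_ladder()) {
    eq <- forager_equilibrium(params, p)
    reg <- productivity_regime(p, 250, 1, params)
    tr <- simulate_forager_dynamics(params, reg, init = c(eq$N, eq$R))
    expect_lt(max(abs(tr$size / eq$N - 1)), 1e-9)
  }
})

test_that("default attractor is a 50-100-yr limit cycle with stable period", {
  tr <- default_cycle_trajectory()
  v <- tr$size
  expect_gt((max(v) - min(v)) / mean(v), 0.2)   # genuinely cycling
  per <- dominant_period(v)
  expect_gte(per, 50); expect_lte(per, 100)
  # period agrees on two disjoint 1000-yr windows within 10%
  p1 <- dominant_period(v[1:1000]); p2 <- dominant_period(v[1001:2000])
  expect_lt(abs(p1 - p2) / p1, 0.10)
})

test_that("long-term mean population increases strictly with productivity", {
  params <- dynamics_params()
  means <- vapply(default_productivity_ladder(), function(p) {
    tr <- simulate_forager_dynamics(params, productivity_regime(p, 2600, 1, params))
    mean(tr$size[601:2600])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_gt(means[4] / means[1], 2)
})

test_that("simulator validates inputs and flags explosions", {
  params <- dynamics_params()
  expect_error(productivity_regime(-1, 100, 1), "positive")
  expect_error(productivity_regime(1, 1, 100), "exceed")
  expect_error(simulate_forager_dynamics(params, productivity_regime(1, 5, 1)), "10 years")
  expect_error(simulate_forager_dynamics(params, productivity_regime(1, 100, 1),
                                         init = c(-1, 5)), "positive")
  expect_error(dynamics_params(cat_rate = 1.5), "cat_rate")
  expect_error(dynamics_params(noise_sd = -1), "noise_sd")
  # near-zero maintenance keeps per-capita growth pinned at a huge r_max:
  # the population outruns any resource feedback and must be flagged
  bad <- dynamics_params(r_max = 5, r_shape = 1e-6, maintenance = 1e-9,
                         g = 50, k0 = 1e6)
  expect_error(simulate_forager_dynamics(bad, productivity_regime(1, 2000, 1, bad),
                                         init = c(1, 1e6)),
               "explosion")
})

test_that("catastrophe model reduces to deterministic logistic growth", {
  params <- dynamics_params(cat_rate = 0, noise_sd = 0, k0 = 300)
  tr <- simulate_catastrophe_dynamics(params, c(2000, 1), init = 10)
  expect_true(all(diff(tr$size) >= -1e-12))          # monotone approach
  expect_lt(abs(tr$size[length(tr$size)] - 300) / 300, 1e-3)
  expect_length(attr(tr, "crash_years"), 0)
})

test_that("crash frequency matches the geometric waiting-time expectation", {
  # rate 1/300 over 30,000 years: ~100 crashes expected (Poisson sd ~10)
  params <- dynamics_params(cat_rate = 1 / 300, noise_sd = 0.05, k0 = 300, seed = 5)
  tr <- simulate_catastrophe_dynamics(params, c(30000, 1))
  crashes <- attr(tr, "crash_years")
  expect_gt(length(crashes), 70)
  expect_lt(length(crashes), 130)
  gaps <- -diff(sort(crashes, decreasing = TRUE))
  expect_gt(mean(gaps), 240)
  expect_lt(mean(gaps), 370)
})

test_that("stochastic simulators are bit-identical under a fixed seed", {
  params <- dynamics_params(cat_rate = 1 / 200, noise_sd = 0.05)
  a <- simulate_catastrophe_dynamics(params, c(5000, 1), seed = 9)
  b <- simulate_catastrophe_dynamics(params, c(5000, 1), seed = 9)
  expect_identical(a$size, b$size)
  expect_identical(attr(a, "crash_years"), attr(b, "crash_years"))
  noisy <- dynamics_params(noise_sd = 0.02)
  reg <- productivity_regime(1, 1000, 1, noisy)
  expect_identical(simulate_forager_dynamics(noisy, reg, seed = 3)$size,
                   simulate_forager_dynamics(noisy, reg, seed = 3)$size)
  # extinction handling: severe frequent crashes with no immigration hit zero
  doom <- dynamics_params(cat_rate = 0.3, cat_severity = 0.95, k0 = 50,
                          r_max = 0.01, seed = 1)
  tr <- simulate_catastrophe_dynamics(doom, c(2000, 1))
  expect_true(any(tr$size == 0))
  expect_equal(tr$size[length(tr$size)], 0)          # absorbing without immigration
})

test_that("concatenate_regimes carries state across regime boundaries", {
  params <- dynamics_params()
  one <- productivity_regime(1, 3000, 1001, params)
  expect_equal(concatenate_regimes(list(one))$size,
               simulate_forager_dynamics(params, one)$size)
  # contiguity enforced
  expect_error(concatenate_regimes(list(
    productivity_regime(1, 3000, 2001, params),
    productivity_regime(1.5, 1999, 1000, params))), "contiguous")
  # two identical regimes: statistically indistinguishable section means
  regs <- list(productivity_regime(1.5, 4000, 2001, params),
               productivity_regime(1.5, 2000, 1, params))
  tr <- concatenate_regimes(regs)
  m <- tapply(tr$size, tr$regime_id, mean)
  expect_lt(abs(m[2] - m[1]) / m[1], 0.05)
  # population is continuous at the boundary (no jump versus cycle scale)
  regs2 <- list(productivity_regime(1, 3000, 2001, params),
                productivity_regime(2.25, 2000, 1, params))
  tr2 <- concatenate_regimes(regs2)
  i <- which(tr2$years_bp == 2001)
  expect_lt(abs(tr2$size[i + 1L] - tr2$size[i]) / tr2$size[i], 0.05)
  # four increasing regimes: section means strictly increasing
  lv <- default_productivity_ladder()
  regs4 <- lapply(seq_along(lv), function(i)
    productivity_regime(lv[i], 10500 - (i - 1) * 1155, 10500 - i * 1155 + 1, params))
  tr4 <- concatenate_regimes(regs4)
  m4 <- tapply(tr4$size, tr4$regime_id, mean)
  expect_true(all(diff(m4) > 0))
})

test_that("tax-record observation follows the binomial sampling contract", {
  traj <- population_trajectory(50:1, rep(120.4, 50))
  exact <- simulate_tax_records(traj, family_size = 1, reporting_prob = 1)
  expect_identical(exact$taxpayers, rep.int(120L, 50))
  expect_identical(simulate_tax_records(traj, 1, 0)$taxpayers, rep.int(0L, 50))
  # binomial expectation: N=500, family 5, reporting 0.9 -> mean ~ 90
  big <- population_trajectory(0:-9999, rep(500, 10000))
  ser <- simulate_tax_records(big, family_size = 5, reporting_prob = 0.9, seed = 2)
  expect_lt(abs(mean(ser$taxpayers) - 90), 0.5)
  # gap years are absent
  gser <- simulate_tax_records(traj, 5, 0.9, gaps = list(c(1910, 1920)), seed = 1)
  expect_false(any(gser$year_ad >= 1910 & gser$year_ad <= 1920))
  expect_error(simulate_tax_records(traj, 5, 1.2), "reporting_prob")
  expect_error(simulate_tax_records(population_trajectory(3000, 5), 5, 1), "AD")
})

test_that("trajectory and tax-record CSV round trips are lossless", {
  tr <- default_cycle_trajectory()
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read_trajectory_csv(f)
  expect_equal(back$years_bp, tr$years_bp)
  expect_equal(back$size, tr$size, tolerance = 1e-12)
  ser <- simulate_tax_records(population_trajectory(100:1, rep(200, 100)),
                              5, 0.9, seed = 1)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_tax_records_csv(ser, f2)
  back2 <- read_tax_records_csv(f2)
  expect_identical(back2$taxpayers, ser$taxpayers)
  expect_identical(back2$year_ad, ser$year_ad)
})
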