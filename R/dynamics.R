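# Population-dynamics simulators: a deterministic consumer--resource map whose
# attractor is a multi-decadal limit cycle controlled by environmental
# productivity, a stochastic logistic model with catastrophic crashes, regime
# concatenation, and synthetic tax-record observation of a trajectory.

#' Interior equilibrium of the consumer--resource map
#'
#' Solves for the fixed point of the forager--resource dynamics: the resource
#' density at which per-capita intake exactly covers maintenance, and the
#' forager density at which harvest balances logistic resource renewal.
#'
#' @param params A [dynamics_params()] set.
#' @param productivity Productivity level; resource carrying capacity is
#'   `params$k0 * productivity`.
#' @return A list with `N` (forager density), `R` (resource density),
#'   `K` (resource carrying capacity) and `intake` (per-capita intake at
#'   equilibrium).
#' @export
forager_equilibrium <- function(params, productivity = 1) {
  stopifnot(inherits(params, "dynamics_params"))
  if (!is_scalar_number(productivity) || productivity <= 0)
    stopf("`productivity` must be a positive scalar")
  istar <- params$maintenance / params$conversion
  denom <- params$attack * (1 - params$handling * istar)
  if (denom <= 0)
    stopf("no interior equilibrium: handling time too large (handling * maintenance/conversion >= 1)")
  c1 <- istar / denom                    # resource density at subsistence, N -> 0
  K <- params$k0 * productivity
  if (c1 >= K)
    stopf("no interior equilibrium: subsistence resource density %.3g exceeds carrying capacity %.3g (increase `k0` or productivity)",
          c1, K)
  w <- params$interference
  g <- params$g * productivity^params$regen_scaling
  if (w == 0) {
    nstar <- g * c1 * (1 - c1 / K) / istar
    rstar <- c1
  } else {
    # with interference, R*(N) = c1 (1 + w N); resource balance gives a quadratic in N
    A <- -g * c1^2 * w^2 / K
    B <- g * c1 * w * (1 - 2 * c1 / K) - istar
    C <- g * c1 * (1 - c1 / K)
    disc <- B^2 - 4 * A * C
    if (disc < 0) stopf("no interior equilibrium for these parameters")
    nstar <- (-B - sqrt(disc)) / (2 * A)   # positive root (A < 0)
    rstar <- c1 * (1 + w * nstar)
    if (nstar <= 0 || rstar >= K) stopf("no interior equilibrium for these parameters")
  }
  list(N = nstar, R = rstar, K = K, intake = istar)
}

# one annual step of the consumer-resource map; state = c(N, R), g already
# scaled by productivity^regen_scaling
forager_step <- function(state, params, K, g, eps = 0) {
  N <- state[[1L]]; R <- state[[2L]]
  a <- params$attack
  intake <- a * R / (1 + a * params$handling * R + params$interference * N)
  phi <- params$r_max * tanh((params$conversion * intake - params$maintenance) / params$r_shape)
  N1 <- N * exp(phi + eps)
  R1 <- R + g * R * (1 - R / K) - N * intake
  R1 <- max(R1, 1e-6 * K)
  c(N1, R1)
}

#' Simulate forager population dynamics under one productivity regime
#'
#' Runs a discrete-time (annual) consumer--resource map: the resource renews
#' logistically with carrying capacity proportional to environmental
#' productivity, foragers harvest it with a Holling type-II functional
#' response, and per-capita population growth is a bounded, saturating
#' function of intake relative to maintenance. Under the default parameters
#' the attractor is a stable limit cycle with a dominant period of 50--100
#' years, a long-term mean that increases with productivity, and
#' trough-to-peak growth-phase rates of 0.4--3\% per year.
#'
#' @param params A [dynamics_params()] set.
#' @param regime A [productivity_regime()]; the simulation covers its years.
#' @param init Optional numeric `c(N, R)` initial state (both positive).
#'   Defaults to the interior equilibrium with the population displaced
#'   upward by 10\%, which places the state on the attracting cycle after a
#'   short transient.
#' @param seed Seed for the multiplicative noise (only used when
#'   `params$noise_sd > 0`); defaults to `params$seed`.
#' @return A [population_trajectory()] over `regime$start_bp..regime$end_bp`,
#'   with the final `c(N, R)` state in attribute `"final_state"`.
#' @export
simulate_forager_dynamics <- function(params, regime, init = NULL, seed = params$seed) {
  stopifnot(inherits(params, "dynamics_params"), inherits(regime, "productivity_regime"))
  n <- regime$start_bp - regime$end_bp + 1L
  if (n < 10L) stopf("regime must span at least 10 years (got %d)", n)
  eq <- forager_equilibrium(params, regime$productivity)
  if (is.null(init)) init <- c(1.1 * eq$N, eq$R)
  if (length(init) != 2L || any(!is.finite(init)) || any(init <= 0))
    stopf("`init` must be two positive scalars c(N, R)")
  eps <- if (params$noise_sd > 0) {
    with_seed(seed, stats::rnorm(n - 1L, 0, params$noise_sd))
  } else numeric(n - 1L)
  g <- params$g * regime$productivity^params$regen_scaling
  N <- numeric(n); R <- numeric(n)
  state <- init
  N[1L] <- state[1L]; R[1L] <- state[2L]
  for (t in seq_len(n - 1L)) {
    state <- forager_step(state, params, eq$K, g, eps[t])
    if (!is.finite(state[1L]) || state[1L] > 1e12)
      stopf("population explosion at year %d cal BP: non-finite or unbounded size; check `r_max`, `g` and `k0` against `attack`/`handling`",
            regime$start_bp - t)
    N[t + 1L] <- state[1L]; R[t + 1L] <- state[2L]
  }
  out <- population_trajectory(regime$start_bp:regime$end_bp, N, regimes = list(regime))
  attr(out, "final_state") <- state
  attr(out, "resource") <- R
  out
}

#' Concatenate productivity regimes into one long trajectory
#'
#' Chains [simulate_forager_dynamics()] across step changes in environmental
#' productivity: each regime is initialised from the final `(N, R)` state of
#' the previous one, so the population is continuous while the carrying
#' capacity jumps.
#'
#' @param regimes List of [productivity_regime()] objects, contiguous and
#'   non-overlapping in cal BP (each `start_bp` one year older than the
#'   previous `end_bp` minus one).
#' @param init Optional initial `c(N, R)` for the first regime.
#' @param seed Optional seed applied across the whole concatenation when any
#'   regime has `noise_sd > 0`.
#' @return A single [population_trajectory()] with per-year `regime_id`.
#' @export
concatenate_regimes <- function(regimes, init = NULL, seed = NULL) {
  if (!length(regimes)) stopf("`regimes` must be a non-empty list")
  for (i in seq_along(regimes)) {
    if (!inherits(regimes[[i]], "productivity_regime"))
      stopf("`regimes[[%d]]` is not a productivity_regime", i)
    if (i > 1L) {
      prev <- regimes[[i - 1L]]$end_bp; cur <- regimes[[i]]$start_bp
      if (cur != prev - 1L)
        stopf("regimes %d and %d are not contiguous: regime %d ends at %d BP but regime %d starts at %d BP",
              i - 1L, i, i - 1L, prev, i, cur)
    }
  }
  run <- function() {
    years <- integer(0); size <- numeric(0); rid <- integer(0)
    state <- init
    for (i in seq_along(regimes)) {
      seg <- simulate_forager_dynamics(regimes[[i]]$params, regimes[[i]],
                                       init = state, seed = NULL)
      state <- attr(seg, "final_state")
      years <- c(years, seg$years_bp)
      size <- c(size, seg$size)
      rid <- c(rid, rep.int(i, length(seg$years_bp)))
    }
    population_trajectory(years, size, regimes = regimes, regime_id = rid)
  }
  with_seed(seed, run())
}

#' Simulate stochastic population dynamics with catastrophic crashes
#'
#' A Ricker (exponential-logistic) map with multiplicative environmental noise
#' and randomly timed catastrophes: each year, with probability
#' `params$cat_rate`, the population loses a Beta-distributed fraction with
#' mean `params$cat_severity`. Populations falling below one individual go
#' locally extinct (size 0) and are optionally re-seeded by
#' `params$immigration` immigrants.
#'
#' @param params A [dynamics_params()] set; uses `r_max` (intrinsic rate),
#'   `k0` (population carrying capacity), `noise_sd`, `cat_rate`,
#'   `cat_severity`, `immigration`.
#' @param span_bp Two integers `c(start_bp, end_bp)` with `start_bp > end_bp`.
#' @param init Initial population size (default `k0 / 2`).
#' @param seed Random seed; defaults to `params$seed`.
#' @return A [population_trajectory()]; crash years are in attribute
#'   `"crash_years"` (cal BP).
#' @export
simulate_catastrophe_dynamics <- function(params, span_bp, init = NULL,
                                          seed = params$seed) {
  stopifnot(inherits(params, "dynamics_params"))
  if (length(span_bp) != 2L) stopf("`span_bp` must be c(start_bp, end_bp)")
  start <- as.integer(round(span_bp[1L])); end <- as.integer(round(span_bp[2L]))
  n <- start - end + 1L
  if (n < 2L) stopf("span must cover at least 1 year of dynamics")
  K <- params$k0
  if (is.null(init)) init <- K / 2
  if (!is_scalar_number(init) || init <= 0) stopf("`init` must be a positive scalar")
  sev_mean <- params$cat_severity
  conc <- 10  # Beta concentration: crashes vary but stay near the mean severity
  run <- function() {
    eps <- if (params$noise_sd > 0) stats::rnorm(n - 1L, 0, params$noise_sd) else numeric(n - 1L)
    crash <- if (params$cat_rate > 0) stats::runif(n - 1L) < params$cat_rate else logical(n - 1L)
    nc <- sum(crash)
    sev <- if (nc > 0) stats::rbeta(nc, sev_mean * conc, (1 - sev_mean) * conc) else numeric(0)
    N <- numeric(n); N[1L] <- init
    k <- 0L
    for (t in seq_len(n - 1L)) {
      x <- N[t]
      x1 <- if (x > 0) x * exp(params$r_max * (1 - x / K) + eps[t]) else 0
      if (crash[t]) { k <- k + 1L; x1 <- x1 * (1 - sev[k]) }
      if (x1 < 1) x1 <- params$immigration
      N[t + 1L] <- x1
    }
    out <- population_trajectory(start:end, N)
    attr(out, "crash_years") <- (start - seq_len(n - 1L))[crash]
    out
  }
  with_seed(seed, run())
}

#' Simulate tax-record observation of a population trajectory
#'
#' Emulates historical taxation ledgers: the population is divided into
#' families, each family owes tax through one adult male, and each potential
#' taxpayer appears in the ledger independently with probability
#' `reporting_prob`. Years inside `gaps` (lost ledgers) are dropped.
#'
#' @param traj A [population_trajectory()] whose years convert to AD
#'   (`AD = 1950 - cal BP`, all resulting years >= 1).
#' @param family_size Assumed persons per taxpaying family (>= 1).
#' @param reporting_prob Probability that a liable adult male is recorded,
#'   in `[0, 1]`.
#' @param gaps List of `c(start_ad, end_ad)` spans with no surviving records.
#' @param seed Random seed for the binomial sampling.
#' @return A [tax_record_series()].
#' @export
simulate_tax_records <- function(traj, family_size = 5, reporting_prob = 0.95,
                                 gaps = list(), seed = NULL) {
  stopifnot(inherits(traj, "population_trajectory"))
  if (!is_scalar_number(family_size) || family_size < 1)
    stopf("`family_size` must be a scalar >= 1")
  if (!is_scalar_number(reporting_prob) || reporting_prob < 0 || reporting_prob > 1)
    stopf("`reporting_prob` must lie in [0, 1]")
  year_ad <- 1950L - traj$years_bp
  if (any(year_ad < 1L)) stopf("trajectory years do not all convert to positive AD years")
  ord <- order(year_ad)
  year_ad <- year_ad[ord]
  liable <- round(traj$size[ord] / family_size)
  counts <- with_seed(seed, stats::rbinom(length(liable), liable, reporting_prob))
  keep <- rep.int(TRUE, length(year_ad))
  for (gap in gaps) keep[year_ad >= min(gap) & year_ad <= max(gap)] <- FALSE
  tax_record_series(year_ad[keep], counts[keep], gap_intervals = gaps)
}

#' Dominant spectral period of a series
#'
#' Raw-periodogram estimate of the dominant oscillation period: the period of
#' the Fourier frequency with maximal power after removing the mean (and,
#' optionally, a linear trend).
#'
#' @param x Numeric series sampled at interval `dt`.
#' @param dt Sampling interval (years).
#' @param detrend Remove a linear trend first? (default TRUE; keeps slow
#'   drifts from masquerading as the dominant cycle).
#' @param max_period Ignore periods longer than this (default `length(x)/2`,
#'   below which a periodogram cannot resolve a full cycle reliably).
#' @return The dominant period in years (NA for a constant series).
#' @export
dominant_period <- function(x, dt = 1, detrend = TRUE, max_period = NULL) {
  n <- length(x)
  if (n < 8L) stopf("series too short for a periodogram")
  if (stats::sd(x) == 0) return(NA_real_)
  y <- if (detrend) stats::residuals(stats::lm(x ~ seq_len(n))) else x - mean(x)
  if (is.null(max_period)) max_period <- n * dt / 2
  p <- Mod(stats::fft(y))^2
  k <- seq_len(floor(n / 2))          # positive Fourier frequencies
  period <- n * dt / k
  ok <- period <= max_period
  k <- k[ok]; period <- period[ok]
  period[which.max(p[k + 1L])]
}
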