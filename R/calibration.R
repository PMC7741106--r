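# Radiocarbon machinery: calibration curves, calibration and back-calibration
# (uncalibration), weighted calendar-date sampling, SPD construction with
# optional taphonomic correction, and the forward SPD simulator that turns a
# "true" population trajectory into its archaeological proxy.

#' A radiocarbon calibration curve
#'
#' Maps calendar age (cal BP) to conventional radiocarbon age with its 1-sigma
#' curve uncertainty, stored ascending in `cal_bp`.
#'
#' @param cal_bp Integer calendar grid, strictly increasing after sorting.
#' @param c14_age Mean radiocarbon age (14C yr BP) per grid point.
#' @param curve_error 1-sigma curve uncertainty (14C yr) per grid point, >= 0.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(cal_bp, c14_age, curve_error) {
  if (length(cal_bp) != length(c14_age) || length(cal_bp) != length(curve_error))
    stopf("curve fields must have equal length")
  if (length(cal_bp) < 2L) stopf("a curve needs at least 2 grid points")
  ord <- order(cal_bp)
  cal_bp <- as.numeric(cal_bp[ord]); c14_age <- as.numeric(c14_age[ord])
  curve_error <- as.numeric(curve_error[ord])
  if (anyDuplicated(cal_bp)) stopf("duplicated cal_bp grid points")
  if (any(!is.finite(c(cal_bp, c14_age, curve_error)))) stopf("non-finite curve values")
  if (any(curve_error < 0)) stopf("`curve_error` must be >= 0")
  structure(list(cal_bp = cal_bp, c14_age = c14_age, curve_error = curve_error),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d points, %s--%s cal BP\n",
              length(x$cal_bp), format(min(x$cal_bp)), format(max(x$cal_bp))))
  invisible(x)
}

#' Read an IntCal-format calibration curve file
#'
#' Parses the standard `.14c` dialect: comma-separated, `#`-prefixed comment
#' header, five columns (CAL BP, 14C age BP, error, Delta14C, sigma
#' Delta14C), rows stored descending in CAL BP. Only the first three columns
#' are kept and the curve is re-sorted ascending in cal BP.
#'
#' @param path Path to a `.14c` file.
#' @return A [calibration_curve()].
#' @export
read_calibration_curve <- function(path) {
  if (!file.exists(path)) stopf("calibration curve file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(data_idx)) stopf("no data rows in %s", path)
  rows <- strsplit(trimws(lines[data_idx]), "\\s*,\\s*")
  out <- matrix(NA_real_, length(rows), 3L)
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 3L)
      stopf("line %d of %s: expected at least 3 comma-separated fields, got %d",
            data_idx[i], path, length(f))
    v <- suppressWarnings(as.numeric(f[1:3]))
    if (any(is.na(v)))
      stopf("line %d of %s: non-numeric value in the first three columns", data_idx[i], path)
    out[i, ] <- v
  }
  calibration_curve(out[, 1L], out[, 2L], out[, 3L])
}

#' Identity calibration curve (test fixture)
#'
#' A curve on which radiocarbon age equals calendar age exactly. Useful for
#' isolating sampling and measurement-error effects from calibration-curve
#' structure in forward simulations.
#'
#' @param cal_bp_min,cal_bp_max Calendar span (inclusive).
#' @param curve_error Constant curve uncertainty (default 0).
#' @return A [calibration_curve()] with `c14_age == cal_bp` pointwise.
#' @export
make_identity_curve <- function(cal_bp_min, cal_bp_max, curve_error = 0) {
  if (cal_bp_max <= cal_bp_min) stopf("`cal_bp_max` must exceed `cal_bp_min`")
  grid <- seq.int(as.integer(cal_bp_min), as.integer(cal_bp_max))
  calibration_curve(grid, grid, rep.int(curve_error, length(grid)))
}

#' Synthetic wiggly calibration curve
#'
#' A purely synthetic stand-in for a real calibration curve: radiocarbon age
#' equals calendar age plus a smooth, autocorrelated "wiggle" process
#' (Gaussian-kernel-smoothed white noise rescaled to `wiggle_sd`), with a
#' constant curve uncertainty. It reproduces the feature of real curves that
#' matters for proxy resolution -- decadal-scale structure that de-phases
#' short-period signal -- without copying any real curve's values.
#'
#' @param cal_bp_min,cal_bp_max Calendar span.
#' @param step Grid spacing in years (real Holocene curves use 5).
#' @param wiggle_sd Standard deviation of the wiggles (14C yr).
#' @param wiggle_length Smoothing length of the wiggle process, in grid steps.
#' @param curve_error Constant 1-sigma curve uncertainty (14C yr).
#' @param seed Seed fixing the wiggle realisation.
#' @return A [calibration_curve()].
#' @export
make_synthetic_curve <- function(cal_bp_min, cal_bp_max, step = 5,
                                 wiggle_sd = 25, wiggle_length = 16,
                                 curve_error = 12, seed = 1) {
  if (cal_bp_max <= cal_bp_min) stopf("`cal_bp_max` must exceed `cal_bp_min`")
  grid <- seq(cal_bp_min, cal_bp_max, by = step)
  wig <- with_seed(seed, {
    raw <- stats::rnorm(length(grid))
    sm <- as.numeric(stats::filter(raw, rep(1, wiggle_length), sides = 2,
                                   circular = TRUE))
    wiggle_sd * (sm - mean(sm)) / stats::sd(sm)
  })
  calibration_curve(grid, grid + wig, rep.int(curve_error, length(grid)))
}

# linear interpolation of curve mean/error at arbitrary calendar ages
curve_at <- function(curve, cal_bp) {
  if (any(cal_bp < min(curve$cal_bp)) || any(cal_bp > max(curve$cal_bp)))
    stopf("calendar age outside the calibration curve span (%s--%s cal BP)",
          format(min(curve$cal_bp)), format(max(curve$cal_bp)))
  list(mu = stats::approx(curve$cal_bp, curve$c14_age, cal_bp)$y,
       err = stats::approx(curve$cal_bp, curve$curve_error, cal_bp)$y)
}

#' Measurement-error model for simulated radiocarbon dates
#'
#' Laboratory 1-sigma errors are drawn from a truncated normal distribution;
#' the defaults (mu 50, sigma 15, truncated to 20--80 14C years) reflect
#' typical reported errors on archaeological charcoal dates.
#'
#' @param mu,sigma Mean and sd of the untruncated normal (14C yr).
#' @param lower,upper Truncation bounds, `lower < upper`.
#' @return An object of class `error_model`.
#' @export
error_model <- function(mu = 50, sigma = 15, lower = 20, upper = 80) {
  if (!is_scalar_number(mu) || !is_scalar_number(sigma) || sigma <= 0)
    stopf("`mu` must be finite and `sigma` positive")
  if (!is_scalar_number(lower) || !is_scalar_number(upper) || lower >= upper)
    stopf("`lower` must be smaller than `upper`")
  structure(list(mu = mu, sigma = sigma, lower = lower, upper = upper),
            class = "error_model")
}

#' Draw truncated-normal lab errors
#'
#' Inverse-CDF sampling (no rejection loop, so draws are seed-stable and
#' vectorised) from the truncated normal of an [error_model()].
#'
#' @param n Number of draws.
#' @param model An [error_model()].
#' @param seed Optional seed.
#' @return Numeric vector of `n` lab errors, all inside `[lower, upper]`.
#' @export
draw_lab_errors <- function(n, model = error_model(), seed = NULL) {
  stopifnot(inherits(model, "error_model"))
  pa <- stats::pnorm(model$lower, model$mu, model$sigma)
  pb <- stats::pnorm(model$upper, model$mu, model$sigma)
  u <- with_seed(seed, stats::runif(n))
  stats::qnorm(pa + u * (pb - pa), model$mu, model$sigma)
}

#' Radiocarbon dates (14C age and lab error)
#'
#' @param c14_age Conventional radiocarbon ages (14C yr BP).
#' @param lab_error 1-sigma measurement errors (> 0), recycled if scalar.
#' @return A data frame of class `radiocarbon_dates` with columns `c14_age`,
#'   `lab_error`.
#' @export
radiocarbon_dates <- function(c14_age, lab_error) {
  lab_error <- rep_len(lab_error, length(c14_age))
  if (any(!is.finite(c14_age)) || any(!is.finite(lab_error)))
    stopf("non-finite date fields")
  if (any(lab_error <= 0)) stopf("`lab_error` must be positive")
  structure(data.frame(c14_age = as.numeric(c14_age),
                       lab_error = as.numeric(lab_error)),
            class = c("radiocarbon_dates", "data.frame"))
}

#' Read/write radiocarbon dates as CSV (`c14_age,lab_error`)
#'
#' @param dates A [radiocarbon_dates()] frame.
#' @param path File path.
#' @return `write_dates_csv()` returns `path` invisibly; `read_dates_csv()`
#'   a `radiocarbon_dates` frame.
#' @export
write_dates_csv <- function(dates, path) {
  utils::write.csv(as.data.frame(dates), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dates_csv
#' @export
read_dates_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("c14_age", "lab_error") %in% names(df)))
    stopf("dates CSV must have columns `c14_age,lab_error`")
  radiocarbon_dates(df$c14_age, df$lab_error)
}

# density of one date over a calendar grid (un-normalized)
date_density <- function(c14_age, lab_error, mu, err) {
  stats::dnorm(c14_age, mu, sqrt(lab_error^2 + err^2))
}

#' Calibrate a radiocarbon date
#'
#' Converts a radiocarbon determination into a probability mass over the
#' calendar grid: at each candidate calendar age the likelihood is the normal
#' density of the measured age about the curve mean, with variance the sum of
#' lab and curve variances; masses are normalised to one.
#'
#' @param date A [radiocarbon_dates()] frame with exactly one row, or a
#'   numeric `c(c14_age, lab_error)`.
#' @param curve A [calibration_curve()].
#' @param resolution Calendar grid step in years (default 1).
#' @return An object of class `calibrated_density` with fields `cal_bp`,
#'   `prob` (summing to one), `c14_age`, `lab_error`.
#' @export
calibrate <- function(date, curve, resolution = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (inherits(date, "radiocarbon_dates")) {
    if (nrow(date) != 1L) stopf("`calibrate()` takes a single date; use build_spd() for many")
    c14 <- date$c14_age; err <- date$lab_error
  } else {
    if (length(date) != 2L) stopf("`date` must be c(c14_age, lab_error)")
    c14 <- date[1L]; err <- date[2L]
  }
  if (err <= 0) stopf("`lab_error` must be positive")
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = resolution)
  cv <- curve_at(curve, grid)
  dens <- date_density(c14, err, cv$mu, cv$err)
  total <- sum(dens)
  if (!is.finite(total) || total <= 0 || max(dens) < 1e-12)
    stopf("date (%.0f +/- %.0f) lies outside the calibration curve: density underflows everywhere",
          c14, err)
  structure(list(cal_bp = grid, prob = dens / total, c14_age = c14, lab_error = err),
            class = "calibrated_density")
}

#' Back-calibrate (uncalibrate) calendar ages into radiocarbon dates
#'
#' The forward-simulation step: each calendar age is mapped through the curve
#' mean (linear interpolation between grid years), a lab error sigma_i is
#' drawn from the truncated normal of the [error_model()], and the
#' radiocarbon age is perturbed by Normal(0, sigma_i) measurement noise (and
#' by Normal(0, curve_error) curve noise where the curve has uncertainty).
#'
#' @param cal_years Calendar ages (cal BP) inside the curve span.
#' @param curve A [calibration_curve()].
#' @param model An [error_model()].
#' @param seed Optional seed.
#' @param perturb Add the measurement noise? `FALSE` attaches drawn errors
#'   without displacing the ages (useful for exact round-trip checks).
#' @return A [radiocarbon_dates()] frame with one row per calendar age.
#' @export
uncalibrate <- function(cal_years, curve, model = error_model(), seed = NULL,
                        perturb = TRUE) {
  stopifnot(inherits(curve, "calibration_curve"), inherits(model, "error_model"))
  cv <- curve_at(curve, cal_years)
  n <- length(cal_years)
  run <- function() {
    sig <- draw_lab_errors(n, model)
    age <- cv$mu
    if (perturb) {
      age <- age + stats::rnorm(n, 0, sig)
      pos <- cv$err > 0
      if (any(pos)) age[pos] <- age[pos] + stats::rnorm(sum(pos), 0, cv$err[pos])
    }
    radiocarbon_dates(age, sig)
  }
  with_seed(seed, run())
}

#' Sample calendar dates weighted by a population trajectory
#'
#' Draws `n` calendar years (with replacement) with probability proportional
#' to population size, restricted to a calendar window -- the "dates as data"
#' assumption that dated archaeological events accrue in proportion to the
#' number of people alive.
#'
#' @param traj A [population_trajectory()].
#' @param n Number of draws (>= 1).
#' @param range_bp `c(bp_old, bp_young)` window inside the trajectory span.
#' @param seed Optional seed.
#' @return Integer vector of `n` calendar years (cal BP).
#' @export
sample_calendar_dates <- function(traj, n, range_bp = NULL, seed = NULL) {
  stopifnot(inherits(traj, "population_trajectory"))
  if (!is_scalar_number(n) || n < 1) stopf("`n` must be >= 1")
  if (is.null(range_bp)) range_bp <- range(traj$years_bp)
  keep <- traj$years_bp <= max(range_bp) & traj$years_bp >= min(range_bp)
  if (!any(keep)) stopf("`range_bp` does not intersect the trajectory")
  yrs <- traj$years_bp[keep]; w <- traj$size[keep]
  if (all(w == 0)) stopf("all trajectory weights are zero inside `range_bp`")
  with_seed(seed, sample(yrs, n, replace = TRUE, prob = w))
}

#' Summed probability distribution of radiocarbon dates
#'
#' Sums the calibrated densities of a set of dates on a common calendar grid.
#' With `normalize = TRUE` (one-date-one-vote followed by division by the
#' number of dates) the SPD has unit total mass.
#'
#' @param dates A [radiocarbon_dates()] frame (>= 1 row).
#' @param curve A [calibration_curve()].
#' @param resolution Calendar grid step in years.
#' @param normalize Normalise each date to unit mass and the sum to one?
#' @return An object of class `spd` with fields `cal_bp`, `prob`, `n_dates`,
#'   `normalized`.
#' @export
build_spd <- function(dates, curve, resolution = 1, normalize = TRUE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!inherits(dates, "radiocarbon_dates")) stopf("`dates` must be a radiocarbon_dates frame")
  if (nrow(dates) < 1L) stopf("`dates` is empty")
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = resolution)
  cv <- curve_at(curve, grid)
  acc <- numeric(length(grid))
  for (i in seq_len(nrow(dates))) {
    dens <- date_density(dates$c14_age[i], dates$lab_error[i], cv$mu, cv$err)
    tot <- sum(dens)
    if (!is.finite(tot) || tot <= 0)
      stopf("date %d (%.0f +/- %.0f) lies outside the calibration curve", i,
            dates$c14_age[i], dates$lab_error[i])
    acc <- acc + if (normalize) dens / tot else dens
  }
  if (normalize) acc <- acc / nrow(dates)
  structure(list(cal_bp = grid, prob = acc, n_dates = nrow(dates),
                 normalized = normalize),
            class = "spd")
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf("<spd> %d dates on %s--%s cal BP (%d grid yr)%s\n",
              x$n_dates, format(max(x$cal_bp)), format(min(x$cal_bp)),
              length(x$cal_bp), if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
as.data.frame.spd <- function(x, ...) data.frame(cal_bp = x$cal_bp, probability = x$prob)

#' Read/write SPDs as CSV (`cal_bp,probability`)
#'
#' @param spd An [build_spd()] `spd` object.
#' @param path File path.
#' @return `write_spd_csv()` returns `path` invisibly; `read_spd_csv()` an
#'   `spd` object (flagged normalized when its mass is within 1e-6 of one).
#' @export
write_spd_csv <- function(spd, path) {
  utils::write.csv(as.data.frame(spd), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spd_csv
#' @export
read_spd_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("cal_bp", "probability") %in% names(df)))
    stopf("SPD CSV must have columns `cal_bp,probability`")
  structure(list(cal_bp = df$cal_bp, prob = df$probability, n_dates = NA_integer_,
                 normalized = abs(sum(df$probability) - 1) < 1e-6),
            class = "spd")
}

#' Restrict an SPD to a calendar window
#'
#' @param spd An [build_spd()] `spd` object.
#' @param range_bp `c(bp_old, bp_young)`, inclusive.
#' @param renormalize Rescale the windowed mass to one?
#' @return The windowed `spd`.
#' @export
window_spd <- function(spd, range_bp, renormalize = FALSE) {
  keep <- spd$cal_bp <= max(range_bp) & spd$cal_bp >= min(range_bp)
  if (!any(keep)) stopf("window does not intersect the SPD grid")
  p <- spd$prob[keep]
  if (renormalize) p <- p / sum(p)
  structure(list(cal_bp = spd$cal_bp[keep], prob = p, n_dates = spd$n_dates,
                 normalized = spd$normalized && renormalize),
            class = "spd")
}

#' Taphonomic correction of an SPD
#'
#' Divides the SPD by a monotone taphonomic survival function of age and
#' renormalises, compensating for the preferential loss of older deposits
#' (older mass is inflated relative to younger). The default survival
#' function is the power-law-with-offset decay commonly fitted to
#' radiocarbon taphonomy, `s(t) = (t + c)^b` up to a constant, with
#' `c = 2176.4` and `b = -1.3925309`.
#'
#' @param spd An [build_spd()] `spd` object on a cal BP grid.
#' @param offset,exponent Constants of the survival law (see above).
#' @param survival Optional custom survival function of cal BP age; must be
#'   positive on the grid. Overrides `offset`/`exponent`.
#' @return The corrected [build_spd()] `spd`, renormalised to the input's total mass.
#' @export
taphonomic_correction <- function(spd, offset = 2176.4, exponent = -1.3925309,
                                  survival = NULL) {
  if (!inherits(spd, "spd")) stopf("`spd` must be an spd object")
  s <- if (is.null(survival)) (spd$cal_bp + offset)^exponent else survival(spd$cal_bp)
  if (any(!is.finite(s)) || any(s <= 0))
    stopf("taphonomic survival function must be positive and finite on the whole grid")
  p <- spd$prob / s
  tot_in <- sum(spd$prob)
  if (tot_in > 0) p <- p * (tot_in / sum(p))
  structure(list(cal_bp = spd$cal_bp, prob = p, n_dates = spd$n_dates,
                 normalized = spd$normalized),
            class = "spd")
}

#' Forward-simulate an SPD from a population trajectory
#'
#' The full proxy-formation protocol: sample calendar dates weighted by the
#' trajectory, back-calibrate them through the curve with truncated-normal
#' lab errors and measurement noise, recalibrate, and sum into an SPD.
#'
#' @param traj A [population_trajectory()].
#' @param n Number of dates (the headline experiment uses 5000).
#' @param range_bp Sampling window `c(bp_old, bp_young)`.
#' @param curve A [calibration_curve()] (identity or IntCal-format).
#' @param model An [error_model()].
#' @param seed Seed making the whole composition reproducible.
#' @param resolution Calendar grid step in years.
#' @param normalize Normalise the SPD to unit mass?
#' @return An [build_spd()] `spd`; the sampled calendar years are kept in attribute
#'   `"calendar_dates"` and the simulated dates in attribute `"dates"`.
#' @export
forward_simulate_spd <- function(traj, n, range_bp, curve, model = error_model(),
                                 seed = NULL, resolution = 1, normalize = TRUE) {
  run <- function() {
    cal <- sample_calendar_dates(traj, n, range_bp)
    dates <- uncalibrate(cal, curve, model)
    out <- build_spd(dates, curve, resolution = resolution, normalize = normalize)
    attr(out, "calendar_dates") <- cal
    attr(out, "dates") <- dates
    out
  }
  with_seed(seed, run())
}
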