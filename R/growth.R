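# Growth-rate estimators: the point formula r = ln(Nt/N0)/t, log-linear
# exponential-model fits, and trough-to-peak segment rates on cyclic series.
#
# Time convention: "forward time" increases toward the present. For series on
# a cal BP axis forward time is -cal_bp, so a positive rate always means
# growth toward the present.

#' A growth-rate estimate
#'
#' Light-weight container for a continuous annual growth rate and its
#' provenance. `rate_percent` is always `100 * rate`; the annualized
#' convention `100 * (exp(rate) - 1)` is available via
#' [annualized_percent()].
#'
#' @param rate Continuous per-year growth rate r.
#' @param interval Two values delimiting the estimate on the series' own time
#'   axis (cal BP for trajectories/SPDs, AD for tax records, plain years
#'   otherwise).
#' @param method One of `"point_formula"`, `"exponential_fit"`, `"segment"`.
#' @param n_points Number of data points used.
#' @param rss Residual sum of squares of the log-linear fit (NA otherwise).
#' @param n_excluded Number of non-positive values excluded from a log fit.
#' @return An object of class `growth_rate_estimate`.
#' @export
growth_rate_estimate <- function(rate, interval, method,
                                 n_points = NA_integer_, rss = NA_real_,
                                 n_excluded = 0L) {
  if (!is_scalar_number(rate)) stopf("`rate` must be a single finite number")
  if (length(interval) != 2L || interval[1L] == interval[2L])
    stopf("`interval` must be two distinct time points")
  method <- match.arg(method, c("point_formula", "exponential_fit", "segment"))
  structure(list(rate = rate, rate_percent = 100 * rate,
                 interval = as.numeric(interval), method = method,
                 n_points = as.integer(n_points), rss = rss,
                 n_excluded = as.integer(n_excluded)),
            class = "growth_rate_estimate")
}

#' @export
print.growth_rate_estimate <- function(x, ...) {
  cat(sprintf("<growth_rate_estimate> %s: r = %.5g /yr (%.3g %%/yr) over [%s, %s]\n",
              x$method, x$rate, x$rate_percent,
              format(x$interval[1L]), format(x$interval[2L])))
  invisible(x)
}

#' @rdname growth_rate_estimate
#' @param x A `growth_rate_estimate`.
#' @export
annualized_percent <- function(x) {
  stopifnot(inherits(x, "growth_rate_estimate"))
  100 * (exp(x$rate) - 1)
}

#' Point growth rate between two census sizes
#'
#' The classical continuous-rate formula `rate = ln(nt/n0)/t_years`.
#'
#' @param n0 Population size at the start of growth (> 0).
#' @param nt Population size after `t_years` (> 0).
#' @param t_years Elapsed time in years (> 0).
#' @return A [growth_rate_estimate()] with method `"point_formula"`.
#' @examples
#' point_growth_rate(100, 1e9, 1611.81)$rate  # ~0.01/yr
#' @export
point_growth_rate <- function(n0, nt, t_years) {
  if (!is_scalar_number(n0) || n0 <= 0) stopf("`n0` must be positive")
  if (!is_scalar_number(nt) || nt <= 0) stopf("`nt` must be positive")
  if (!is_scalar_number(t_years) || t_years <= 0) stopf("`t_years` must be positive")
  growth_rate_estimate(log(nt / n0) / t_years, c(0, t_years), "point_formula",
                       n_points = 2L)
}

#' Time for a population to reach a target size at a constant rate
#'
#' Inverse of the point formula: `years = ln(target / n0) / rate`. At
#' ethnographic hunter--gatherer rates (1--3 \%/yr) 100 foragers pass one
#' billion in well under 2000 years -- the forager population paradox.
#'
#' @param n0 Starting size (> 0).
#' @param target Target size (>= `n0`).
#' @param rate Continuous annual growth rate (> 0).
#' @return Years to reach the target (0 when `target == n0`).
#' @examples
#' time_to_size(100, 1e9, 0.01)  # ~1611.8 years
#' @export
time_to_size <- function(n0, target, rate) {
  if (!is_scalar_number(n0) || n0 <= 0) stopf("`n0` must be positive")
  if (!is_scalar_number(target) || target < n0) stopf("`target` must be >= `n0`")
  if (!is_scalar_number(rate) || rate <= 0) stopf("`rate` must be positive")
  log(target / n0) / rate
}

# ---- exponential-model fits -------------------------------------------------

# core log-linear OLS on forward time; interval reported on the original axis
fit_exp_core <- function(time_fwd, value, interval_axis) {
  ok <- is.finite(value) & value > 0
  n_excluded <- sum(!ok)
  t <- time_fwd[ok]; v <- value[ok]
  if (length(v) < 3L)
    stopf("need at least 3 positive points for an exponential fit (got %d usable)", length(v))
  fit <- stats::lm.fit(cbind(1, t), log(v))
  growth_rate_estimate(unname(fit$coefficients[2L]), interval_axis,
                       "exponential_fit", n_points = length(v),
                       rss = sum(fit$residuals^2), n_excluded = n_excluded)
}

#' Fit an exponential growth model to a time-indexed series
#'
#' Ordinary least squares of `log(value)` on forward time (years increasing
#' toward the present), the standard way growth rates are extracted from
#' population proxies. Zero or negative values are excluded (never floored)
#' and their count reported in `n_excluded`.
#'
#' @param x A series: a numeric time vector (with `value`), a
#'   [population_trajectory()], an [build_spd()] `spd` object, or a [tax_record_series()].
#' @param value Numeric values when `x` is a plain time vector.
#' @param interval Optional window on the series' own axis: `c(bp_old,
#'   bp_young)` for cal BP series, `c(ad_from, ad_to)` for tax records,
#'   `c(from, to)` otherwise.
#' @param ... Passed between methods.
#' @return A [growth_rate_estimate()] with method `"exponential_fit"`.
#' @export
fit_exponential <- function(x, ...) UseMethod("fit_exponential")

#' @rdname fit_exponential
#' @export
fit_exponential.default <- function(x, value, interval = NULL, ...) {
  if (length(x) != length(value)) stopf("`x` (time) and `value` lengths differ")
  if (is.null(interval)) interval <- range(x)
  keep <- x >= min(interval) & x <= max(interval)
  fit_exp_core(x[keep], value[keep], interval)
}

#' @rdname fit_exponential
#' @export
fit_exponential.population_trajectory <- function(x, interval = NULL, ...) {
  if (is.null(interval)) interval <- c(x$years_bp[1L], x$years_bp[length(x$years_bp)])
  keep <- x$years_bp <= max(interval) & x$years_bp >= min(interval)
  fit_exp_core(-x$years_bp[keep], x$size[keep], interval)
}

#' @rdname fit_exponential
#' @export
fit_exponential.spd <- function(x, interval = NULL, ...) {
  if (is.null(interval)) interval <- c(max(x$cal_bp), min(x$cal_bp))
  keep <- x$cal_bp <= max(interval) & x$cal_bp >= min(interval)
  fit_exp_core(-x$cal_bp[keep], x$prob[keep], interval)
}

#' @rdname fit_exponential
#' @export
fit_exponential.tax_record_series <- function(x, interval = NULL, ...) {
  if (is.null(interval)) interval <- range(x$year_ad)
  keep <- x$year_ad >= min(interval) & x$year_ad <= max(interval)
  fit_exp_core(x$year_ad[keep], x$taxpayers[keep], interval)
}

# ---- growth-phase segmentation ----------------------------------------------

# alternating local extrema of v whose vertical movement exceeds thr
# (classic zigzag/peak-valley filter); returns indices
find_extrema <- function(v, thr) {
  n <- length(v)
  ext <- integer(0); dir <- 0L
  cur_min <- v[1L]; cur_min_i <- 1L
  cur_max <- v[1L]; cur_max_i <- 1L
  for (i in seq.int(2L, n)) {
    x <- v[i]
    if (x > cur_max) { cur_max <- x; cur_max_i <- i }
    if (x < cur_min) { cur_min <- x; cur_min_i <- i }
    if (dir <= 0L && x - cur_min >= thr) {
      ext <- c(ext, cur_min_i); dir <- 1L
      cur_max <- x; cur_max_i <- i
    } else if (dir >= 0L && cur_max - x >= thr) {
      ext <- c(ext, cur_max_i); dir <- -1L
      cur_min <- x; cur_min_i <- i
    }
  }
  if (dir == 1L) ext <- c(ext, cur_max_i)
  if (dir == -1L) ext <- c(ext, cur_min_i)
  ext
}

# core segmentation on forward time; axis_time maps indices back to the
# series' own axis for reporting
segment_core <- function(time_fwd, value, prominence, axis_time) {
  n <- length(value)
  if (n < 3L) stopf("series must have at least 3 points")
  rng <- max(value) - min(value)
  if (rng <= 0) return(list())
  ext <- find_extrema(value, prominence * rng)
  if (length(ext) < 2L) return(list())
  out <- list()
  for (j in seq_len(length(ext) - 1L)) {
    i1 <- ext[j]; i2 <- ext[j + 1L]
    if (value[i2] > value[i1] && value[i1] > 0) {   # trough -> peak only
      r <- log(value[i2] / value[i1]) / (time_fwd[i2] - time_fwd[i1])
      out[[length(out) + 1L]] <-
        growth_rate_estimate(r, c(axis_time[i1], axis_time[i2]), "segment",
                             n_points = i2 - i1 + 1L)
    }
  }
  out
}

#' Growth rates of trough-to-peak growth phases
#'
#' Detects alternating local extrema whose movement exceeds `prominence`
#' times the series range (a zigzag filter, so small wiggles and observation
#' noise are ignored) and reports the point growth rate of every trough-to-
#' peak (growth-phase) segment. This is how annual growth rates "during
#' growth periods" are measured on cyclic population series.
#'
#' @inheritParams fit_exponential
#' @param prominence Minimum extremum-to-extremum movement as a fraction of
#'   the series range (default 0.1).
#' @return A list of [growth_rate_estimate()] objects (empty for a constant
#'   or extremum-free series).
#' @export
segment_growth_rates <- function(x, ...) UseMethod("segment_growth_rates")

#' @rdname segment_growth_rates
#' @export
segment_growth_rates.default <- function(x, value, prominence = 0.1, ...) {
  if (length(x) != length(value)) stopf("`x` (time) and `value` lengths differ")
  segment_core(x, value, prominence, x)
}

#' @rdname segment_growth_rates
#' @export
segment_growth_rates.population_trajectory <- function(x, prominence = 0.1, ...) {
  segment_core(-x$years_bp, x$size, prominence, x$years_bp)
}

#' @rdname segment_growth_rates
#' @export
segment_growth_rates.spd <- function(x, prominence = 0.1, ...) {
  segment_core(-x$cal_bp, x$prob, prominence, x$cal_bp)
}

#' @rdname segment_growth_rates
#' @export
segment_growth_rates.tax_record_series <- function(x, prominence = 0.1, ...) {
  segment_core(x$year_ad, as.numeric(x$taxpayers), prominence, x$year_ad)
}
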