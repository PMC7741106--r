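# Core containers for "true" population histories: parameter sets, productivity
# regimes, annual trajectories on a cal BP axis, and historical tax-record series.

#' Parameters of the population-dynamics simulators
#'
#' Bundles every rate used by [simulate_forager_dynamics()] (a discrete-time
#' consumer--resource map) and [simulate_catastrophe_dynamics()] (a stochastic
#' logistic map with catastrophic crashes). All rates are per year.
#'
#' @param r_max Maximum per-capita population growth rate (1/yr). Bounds both
#'   growth and decline of the forager population.
#' @param r_shape Width (in intake units) of the saturating growth response:
#'   per-capita growth is `r_max * tanh((conversion * intake - maintenance) / r_shape)`.
#'   Small values give a switch-like response and relaxation-type cycles.
#' @param g Resource regeneration rate (1/yr) of the logistic resource renewal.
#' @param k0 Carrying-capacity scale. In the consumer--resource map the resource
#'   carrying capacity is `k0 * productivity_level`; in the catastrophe model it
#'   is the population carrying capacity itself.
#' @param attack Harvest (encounter) rate of foragers on the resource (1/yr).
#' @param handling Handling time per unit resource harvested (yr).
#' @param conversion Efficiency converting intake into the growth response.
#' @param maintenance Per-capita maintenance intake; intake above it allows
#'   growth, below it forces decline.
#' @param regen_scaling Exponent with which productivity scales the resource
#'   regeneration rate: effective regeneration is `g * productivity^regen_scaling`
#'   while carrying capacity is `k0 * productivity`. With the default 1,
#'   productivity acts on the production flux, so equilibrium forager density
#'   scales close to linearly with productivity.
#' @param interference Density-dependence (interference) strength: per-capita
#'   intake is `attack * R / (1 + attack * handling * R + interference * N)`
#'   (a Beddington--DeAngelis response). Larger values damp the
#'   paradox-of-enrichment and make mean population size scale more closely
#'   with productivity.
#' @param noise_sd Standard deviation of multiplicative (log-scale) annual
#'   demographic/environmental noise. 0 gives deterministic dynamics.
#' @param cat_rate Probability per year of a catastrophic crash
#'   (catastrophe model only). Must lie in `[0, 1)`.
#' @param cat_severity Mean fraction of the population lost in a crash, in
#'   (0, 1). Realised severities are Beta-distributed around this mean.
#' @param immigration Number of immigrants re-seeding the population after it
#'   falls below one individual (0 makes extinction absorbing).
#' @param seed Default random seed used by stochastic simulators when no seed
#'   is given at call time; `NULL` leaves the RNG state alone.
#'
#' @details The default values were tuned numerically (see
#'   `tools/tune_dynamics.R` in the package sources) so that, across the
#'   default four-level productivity ladder, the attractor of
#'   [simulate_forager_dynamics()] is a stable limit cycle with a dominant
#'   period of 50--100 years, trough-to-peak growth-phase rates between 0.4
#'   and 3 percent per year, and a long-term mean that increases strictly
#'   with productivity.
#'
#' @return An object of class `dynamics_params` (a named list).
#' @seealso [forager_equilibrium()], [simulate_forager_dynamics()]
#' @export
dynamics_params <- function(r_max = 0.03, r_shape = 2, g = 2.36, k0 = 720,
                            attack = 0.05, handling = 0.05, conversion = 1,
                            maintenance = 1, interference = 0.0075,
                            regen_scaling = 0.62, noise_sd = 0,
                            cat_rate = 1 / 300, cat_severity = 0.75,
                            immigration = 0, seed = NULL) {
  p <- list(r_max = r_max, r_shape = r_shape, g = g, k0 = k0, attack = attack,
            handling = handling, conversion = conversion, maintenance = maintenance,
            interference = interference, regen_scaling = regen_scaling,
            noise_sd = noise_sd, cat_rate = cat_rate,
            cat_severity = cat_severity, immigration = immigration, seed = seed)
  for (nm in setdiff(names(p), "seed")) {
    if (!is_scalar_number(p[[nm]])) stopf("parameter `%s` must be a single finite number", nm)
  }
  if (p$r_max <= 0) stopf("`r_max` must be positive")
  if (p$r_shape <= 0) stopf("`r_shape` must be positive")
  if (p$g <= 0 || p$k0 <= 0 || p$attack <= 0) stopf("`g`, `k0` and `attack` must be positive")
  if (p$handling < 0 || p$conversion <= 0 || p$maintenance <= 0)
    stopf("`handling` must be >= 0; `conversion` and `maintenance` positive")
  if (p$interference < 0) stopf("`interference` must be >= 0")
  if (p$regen_scaling < 0 || p$regen_scaling > 2) stopf("`regen_scaling` must lie in [0, 2]")
  if (p$noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (p$cat_rate < 0 || p$cat_rate >= 1) stopf("`cat_rate` must lie in [0, 1)")
  if (p$cat_severity <= 0 || p$cat_severity >= 1) stopf("`cat_severity` must lie in (0, 1)")
  if (p$immigration < 0) stopf("`immigration` must be >= 0")
  structure(p, class = "dynamics_params")
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat("<dynamics_params>\n")
  flat <- unlist(x[!vapply(x, is.null, logical(1L))])
  cat(paste0("  ", names(flat), " = ", signif(flat, 5), collapse = "\n"), "\n")
  invisible(x)
}

#' An environmental-productivity regime
#'
#' A contiguous block of calendar time (cal BP) during which environmental
#' productivity -- and hence the resource carrying capacity of the
#' consumer--resource model -- is constant.
#'
#' @param productivity Positive scalar productivity level (abstract units,
#'   proportional to resource carrying capacity).
#' @param start_bp,end_bp Calendar bounds in years cal BP (integers). `start_bp`
#'   is the older end, so `start_bp > end_bp`.
#' @param params A [dynamics_params()] set governing dynamics inside the regime.
#'
#' @return An object of class `productivity_regime`.
#' @export
productivity_regime <- function(productivity, start_bp, end_bp,
                                params = dynamics_params()) {
  if (!is_scalar_number(productivity) || productivity <= 0)
    stopf("`productivity` must be a positive scalar")
  if (!is_scalar_number(start_bp) || !is_scalar_number(end_bp))
    stopf("`start_bp` and `end_bp` must be single numbers")
  start_bp <- as.integer(round(start_bp)); end_bp <- as.integer(round(end_bp))
  if (start_bp <= end_bp)
    stopf("`start_bp` (%d) must exceed `end_bp` (%d): cal BP decreases toward the present",
          start_bp, end_bp)
  if (!inherits(params, "dynamics_params")) stopf("`params` must be a dynamics_params object")
  structure(list(productivity = productivity, start_bp = start_bp,
                 end_bp = end_bp, params = params),
            class = "productivity_regime")
}

#' @export
print.productivity_regime <- function(x, ...) {
  cat(sprintf("<productivity_regime> level %.4g over %d--%d cal BP (%d yr)\n",
              x$productivity, x$start_bp, x$end_bp, x$start_bp - x$end_bp + 1L))
  invisible(x)
}

#' An annual population trajectory on a cal BP axis
#'
#' @param years_bp Integer calendar years cal BP, strictly decreasing with an
#'   exact annual step (past to present reading left to right).
#' @param size Non-negative population size/density, one value per year.
#' @param regimes Optional list of [productivity_regime()] objects covering the
#'   grid; used for per-regime summaries and provenance.
#' @param regime_id Optional integer vector assigning each year to an entry of
#'   `regimes`.
#'
#' @return An object of class `population_trajectory` with fields `years_bp`,
#'   `size`, `regimes`, `regime_id`.
#' @export
population_trajectory <- function(years_bp, size, regimes = NULL, regime_id = NULL) {
  years_bp <- as.integer(round(years_bp))
  if (length(years_bp) != length(size))
    stopf("`years_bp` and `size` must have the same length")
  if (length(years_bp) < 1L) stopf("empty trajectory")
  if (length(years_bp) > 1L && any(diff(years_bp) != -1L))
    stopf("`years_bp` must decrease by exactly 1 year per step")
  if (any(!is.finite(size)) || any(size < 0))
    stopf("`size` must be finite and non-negative everywhere")
  if (is.null(regime_id)) regime_id <- rep.int(1L, length(years_bp))
  structure(list(years_bp = years_bp, size = as.numeric(size),
                 regimes = regimes, regime_id = as.integer(regime_id)),
            class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf("<population_trajectory> %d--%d cal BP (%d yr), size %.4g--%.4g, %d regime(s)\n",
              x$years_bp[1L], x$years_bp[length(x$years_bp)], length(x$years_bp),
              min(x$size), max(x$size),
              if (is.null(x$regimes)) 1L else length(x$regimes)))
  invisible(x)
}

#' @export
as.data.frame.population_trajectory <- function(x, ...) {
  data.frame(cal_bp = x$years_bp, size = x$size, regime_id = x$regime_id)
}

#' Restrict a trajectory to a calendar window
#'
#' @param traj A [population_trajectory()].
#' @param range_bp Two values `c(bp_old, bp_young)`, inclusive.
#' @return The windowed `population_trajectory`.
#' @export
window_trajectory <- function(traj, range_bp) {
  stopifnot(inherits(traj, "population_trajectory"))
  old <- max(range_bp); young <- min(range_bp)
  keep <- traj$years_bp <= old & traj$years_bp >= young
  if (!any(keep)) stopf("window [%s, %s] does not intersect the trajectory", old, young)
  population_trajectory(traj$years_bp[keep], traj$size[keep],
                        regimes = traj$regimes, regime_id = traj$regime_id[keep])
}

#' Read/write trajectories as CSV
#'
#' The on-disk format has a header and columns `cal_bp,size,regime_id`,
#' one row per year.
#'
#' @param traj A [population_trajectory()].
#' @param path File path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a `population_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "population_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cal_bp", "size")
  if (!all(need %in% names(df)))
    stopf("trajectory CSV must have columns `cal_bp,size` (got: %s)",
          paste(names(df), collapse = ","))
  rid <- if ("regime_id" %in% names(df)) df$regime_id else NULL
  population_trajectory(df$cal_bp, df$size, regime_id = rid)
}

#' An annual tax-record series (taxpayer counts, AD years)
#'
#' Historical tax ledgers count taxpaying adult males annually; the count is a
#' population-size proxy. Years falling inside `gap_intervals` (lost records)
#' are absent from the series.
#'
#' @param year_ad Integer calendar years AD, strictly increasing; gaps allowed.
#' @param taxpayers Non-negative integer counts, one per year.
#' @param gap_intervals List of `c(start_ad, end_ad)` spans of missing records.
#' @return An object of class `tax_record_series`.
#' @export
tax_record_series <- function(year_ad, taxpayers, gap_intervals = list()) {
  year_ad <- as.integer(round(year_ad))
  if (length(year_ad) != length(taxpayers)) stopf("`year_ad` and `taxpayers` lengths differ")
  if (length(year_ad) > 1L && any(diff(year_ad) <= 0L)) stopf("`year_ad` must be strictly increasing")
  taxpayers <- as.integer(round(taxpayers))
  if (any(!is.finite(taxpayers)) || any(taxpayers < 0L)) stopf("`taxpayers` must be non-negative integers")
  for (gap in gap_intervals) {
    if (length(gap) != 2L) stopf("each gap interval must be c(start_ad, end_ad)")
    if (any(year_ad >= min(gap) & year_ad <= max(gap)))
      stopf("years inside the gap %d--%d are present in the series", min(gap), max(gap))
  }
  structure(list(year_ad = year_ad, taxpayers = taxpayers,
                 gap_intervals = gap_intervals),
            class = "tax_record_series")
}

#' @export
print.tax_record_series <- function(x, ...) {
  cat(sprintf("<tax_record_series> AD %d--%d, %d records, %d gap(s)\n",
              x$year_ad[1L], x$year_ad[length(x$year_ad)], length(x$year_ad),
              length(x$gap_intervals)))
  invisible(x)
}

#' @export
as.data.frame.tax_record_series <- function(x, ...) {
  data.frame(year_ad = x$year_ad, taxpayers = x$taxpayers)
}

#' Read/write tax-record series as CSV (`year_ad,taxpayers`)
#'
#' @param series A [tax_record_series()].
#' @param path File path.
#' @return `write_tax_records_csv()` returns `path` invisibly;
#'   `read_tax_records_csv()` a `tax_record_series`.
#' @export
write_tax_records_csv <- function(series, path) {
  stopifnot(inherits(series, "tax_record_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tax_records_csv
#' @export
read_tax_records_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("year_ad", "taxpayers") %in% names(df)))
    stopf("tax-record CSV must have columns `year_ad,taxpayers`")
  tax_record_series(df$year_ad, df$taxpayers)
}
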