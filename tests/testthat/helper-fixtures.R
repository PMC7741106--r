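# shared fixtures, built in code (no binary files)

# minimal IntCal-dialect curve file: 3 rows, stored descending as in the
# standard files
write_mini_curve_file <- function(path, rows = NULL) {
  if (is.null(rows))
    rows <- c("300,310,8,0,0", "200,205,8,0,0", "100,98,8,0,0")
  writeLines(c("# synthetic mini curve", "# CAL BP, 14C age, Error, D14C, Sigma", rows), path)
  path
}

# a small cyclic trajectory from the default simulator (memoised per session)
default_cycle_trajectory <- local({
  cache <- NULL
  function(years = 2000, burn = 500, productivity = 1) {
    if (!is.null(cache)) return(cache)
    reg <- productivity_regime(productivity, years + burn, 1, dynamics_params())
    tr <- simulate_forager_dynamics(dynamics_params(), reg)
    cache <<- window_trajectory(tr, c(years, 1))
    cache
  }
})

# tiny experiment configuration for pipeline smoke tests
smoke_config <- function(...) {
  experiment_config(productivity_levels = c(1, 1.5), shift_bp = 8500,
                    range_bp = c(8700, 8300), burn_in = 300, n_dates = 50,
                    n_replicates = 1, n_sim = 5, period_range = c(8, 128),
                    seed = 11, ...)
}
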