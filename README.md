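# spdproxy

Population dynamics and their radiocarbon-date proxies: what can a summed
probability distribution (SPD) of archaeological radiocarbon dates actually
resolve about the population history that generated it?

## The problem

Census-based estimates of hunter-gatherer population growth (ethnographic
and historical) run at 1–3 %/yr during growth periods. Growth rates fitted
to archaeological SPDs run at 0.01–0.3 %/yr — orders of magnitude smaller.
Taken at face value the census rates are impossible over prehistory: at
r = 0.01/yr, 100 foragers reach 10⁹ in

    t = ln(N_t / N_0) / r = ln(10⁷) / 0.01 ≈ 1612 years

(the *forager population paradox*). `spdproxy` implements the full
simulation argument that the two kinds of estimate measure different
things. It provides:

* **Synthetic truths** — a discrete-time consumer–resource map
  (logistic resource renewal, Beddington–DeAngelis harvest, bounded
  saturating growth response) whose attractor is a stable limit cycle with
  a 50–100-yr period; mean density, amplitude and growth-phase rate are
  controlled by environmental productivity. Plus a stochastic
  catastrophe model and a scripted early-modern tax-record scenario.
* **Proxy formation** — calibration-curve handling (IntCal-format `.14c`
  files, identity and synthetic wiggly curves), back-calibration with
  truncated-normal lab errors (μ = 50, σ = 15, bounds 20–80 ¹⁴C yr),
  calibration, SPD summation, optional taphonomic correction.
* **Measurement** — the point formula r = ln(Nt/N0)/t, log-linear
  exponential fits, trough-to-peak growth-phase segmentation, and Morlet
  wavelet coherence with Monte-Carlo (AR(1), phase, or white-noise
  surrogate) significance and cone-of-influence handling.
* **Experiments** — `run_headline_experiment()` (truth → repeated SPDs →
  rates, trend correlations, coherence scale profiles),
  `run_productivity_contrast()` (constant vs rising productivity),
  `run_tax_record_analysis()` (growth phases of synthetic taxpayer
  counts), with JSON/CSV reports carrying full provenance.

## Worked example

```r
library(spdproxy)

# the paradox arithmetic
time_to_size(100, 1e9, 0.01)
#> [1] 1611.81

# a "true" population history: default limit cycle, 2000 yr after burn-in
params <- dynamics_params()
truth  <- window_trajectory(
  simulate_forager_dynamics(params, productivity_regime(1, 2500, 1, params)),
  c(2000, 1))
dominant_period(truth$size)
#> [1] 57.14286

segs <- segment_growth_rates(truth)
range(vapply(segs, `[[`, numeric(1), "rate_percent"))
#> [1] 1.90 2.09          # 35 growth phases at ~2 %/yr — the census view

fit_exponential(truth)$rate_percent
#> [1] -0.00032           # whole-range rate ~0 — the series is stationary

# what the archaeological instrument sees: 2000 dates through an
# error-free calibration curve
curve <- make_identity_curve(1, 2600)
spd <- window_spd(
  forward_simulate_spd(truth, 2000, c(1900, 100), curve, seed = 1),
  c(1900, 100))
fit_exponential(spd)$rate_percent
#> [1] -0.00115           # the SPD also sees only the (flat) long-term mean
length(segment_growth_rates(spd))
#> [1] 4                  # the ~35 true growth phases are gone
```

The within-cycle growth that dominates the census view (≈2 %/yr) is
invisible to the SPD, whose fitted rate reflects the long-term mean — in
the four-regime headline experiment, the environmental-productivity trend
(~0.05 %/yr from the SPD against segment rates up to 2.7 %/yr in the
truth). Wavelet coherence locates the agreement between truth and proxy at
the ~1000-yr regime-shift scale, not at the 50–100-yr cycle scale. See
`vignettes/proxy-resolution.Rmd` for the model, its assumptions, and known
limitations.

## Command line

An installed `exec/spdproxy` script exposes subcommands
(`calibrate`, `uncalibrate`, `spd`, `forward-spd`, `growth-rate`,
`coherence`, `run-experiment`, `run-contrast`, `run-taxrecords`); run
`spdproxy help` for flags. Experiment configs are JSON mirrors of
`experiment_config()` arguments.

## Data

No real data ship with the package. `inst/extdata/synthetic_calcurve.14c`
is a *synthetic* IntCal-dialect fixture (identity mapping plus smooth
autocorrelated wiggles); `inst/extdata/growth_rate_estimates_literature.csv`
is a small static reference table of published ethnographic and
archaeological growth-rate estimates.
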