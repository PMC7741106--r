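# Morlet continuous wavelet transform, wavelet coherence with
# Torrence-Webster style smoothing, Monte-Carlo significance against AR(1)
# surrogates, and per-period significance profiles. FFT-based throughout.

morlet_fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

# frequency-domain Morlet daughters (pad x n_scales), cached: the significance
# Monte Carlo reuses one geometry hundreds of times
.daughter_cache <- new.env(parent = emptyenv())
morlet_daughters <- function(pad, dt, scales, omega0) {
  key <- paste(pad, dt, omega0, length(scales), scales[1L], scales[length(scales)],
               sep = "|")
  hit <- .daughter_cache[[key]]
  if (!is.null(hit)) return(hit)
  wk <- 2 * pi * seq.int(0L, pad - 1L) / (pad * dt)
  wk[wk > pi / dt] <- wk[wk > pi / dt] - 2 * pi / dt
  pos <- wk > 0
  d <- matrix(0, pad, length(scales))
  norm0 <- pi^(-0.25)
  for (j in seq_along(scales)) {
    s <- scales[j]
    d[pos, j] <- sqrt(2 * pi * s / dt) * norm0 * exp(-0.5 * (s * wk[pos] - omega0)^2)
  }
  if (length(ls(.daughter_cache)) > 8L) rm(list = ls(.daughter_cache), envir = .daughter_cache)
  .daughter_cache[[key]] <- d
  d
}

#' Morlet continuous wavelet transform
#'
#' FFT-based CWT with a Morlet mother wavelet (default omega0 = 6) on a
#' dyadic scale ladder with `dj` sub-octaves, following the standard
#' Torrence--Compo construction (zero padding to the next power of two,
#' analytic daughter wavelets in the frequency domain).
#'
#' @param x Evenly spaced numeric series, length >= 32.
#' @param dt Sampling interval in years.
#' @param dj Scale resolution in octaves (default 1/20).
#' @param period_range Optional `c(min, max)` periods (years) to analyse;
#'   defaults to `c(2 * dt, n * dt)`.
#' @param omega0 Morlet non-dimensional frequency.
#' @param standardize Centre and scale the series first? Default `FALSE`, so
#'   the transform is linear in its input; [coherence()] standardizes its
#'   own inputs.
#' @return An object of class `morlet_cwt`: complex coefficient matrix `coef`
#'   (scales x times), `scales`, `periods` (years), `coi` (maximum reliable
#'   period per time step), `dt`, `dj`, `omega0`.
#' @export
cwt <- function(x, dt = 1, dj = 1 / 20, period_range = NULL, omega0 = 6,
                standardize = FALSE) {
  n <- length(x)
  if (n < 32L) stopf("series must have at least 32 points (got %d)", n)
  if (any(!is.finite(x))) stopf("series contains non-finite values")
  if (dt <= 0 || dj <= 0) stopf("`dt` and `dj` must be positive")
  if (standardize) {
    s <- stats::sd(x)
    x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  }
  ff <- morlet_fourier_factor(omega0)
  if (is.null(period_range)) period_range <- c(2 * dt, n * dt)
  s0 <- max(2 * dt, min(period_range) / ff)
  smax <- max(period_range) / ff
  J <- max(0L, floor(log2(smax / s0) / dj))
  scales <- s0 * 2^(dj * (0:J))
  pad <- 2^ceiling(log2(n))
  if (pad < 1.5 * n) pad <- 2L * pad
  fx <- stats::fft(c(x - mean(x), numeric(pad - n)))
  daughters <- morlet_daughters(pad, dt, scales, omega0)
  coef <- t(stats::mvfft(daughters * fx, inverse = TRUE))[, seq_len(n), drop = FALSE] / pad
  dist <- dt * (pmin(seq_len(n) - 1L, n - seq_len(n)) + 0.5)
  coi <- ff / sqrt(2) * dist
  structure(list(coef = coef, scales = scales, periods = ff * scales,
                 coi = coi, dt = dt, dj = dj, omega0 = omega0, n = n),
            class = "morlet_cwt")
}

#' @export
print.morlet_cwt <- function(x, ...) {
  cat(sprintf("<morlet_cwt> %d scales (periods %.3g--%.3g yr) x %d times\n",
              length(x$scales), min(x$periods), max(x$periods), x$n))
  invisible(x)
}

# lag-1 autocorrelation, clamped to the stationary range
ar1_coef <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  r <- sum(x[-1] * x[-n]) / sum(x^2)
  min(max(r, 0), 0.9999)
}

# stationary AR(1) surrogate of length n
ar1_surrogate <- function(n, rho) {
  innov <- stats::rnorm(n)
  x <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                init = stats::rnorm(1) / sqrt(1 - rho^2)))
  x
}

# Fourier phase-randomized surrogate: preserves the series' power spectrum
# exactly, randomizes phases (Hermitian-symmetric)
phase_surrogate <- function(x) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  half <- (n - 1L) %/% 2L
  if (half > 0L) {
    idx <- seq.int(2L, half + 1L)
    ph <- stats::runif(half, 0, 2 * pi)
    X[idx] <- Mod(X[idx]) * exp(1i * ph)
    X[n + 2L - idx] <- Conj(X[idx])
  }
  if (n %% 2L == 0L) X[n / 2L + 1L] <- Mod(X[n / 2L + 1L]) * sign(stats::runif(1) - 0.5)
  Re(stats::fft(X, inverse = TRUE)) / n
}

# smoothing operator: scale-proportional boxcar in time, fixed-octave boxcar
# across scales; m is a scales x times matrix (real)
smooth_wavelet <- function(m, scales, dt, dj, time_factor = 1, scale_octaves = 0.6) {
  for (j in seq_along(scales)) {
    h <- max(1L, as.integer(round(time_factor * scales[j] / (2 * dt))))
    m[j, ] <- running_mean(m[j, ], h)
  }
  hs <- max(1L, as.integer(round(scale_octaves / (2 * dj))))
  running_mean_rows(m, hs)
}

# coherence core on two standardized series; returns list(coh, periods, coi, ...)
coherence_core <- function(x, y, dt, dj, period_range, omega0,
                           time_factor, scale_octaves) {
  wx <- cwt(x, dt, dj, period_range, omega0, standardize = TRUE)
  wy <- cwt(y, dt, dj, period_range, omega0, standardize = TRUE)
  sinv <- 1 / wx$scales
  px <- smooth_wavelet(sinv * Mod(wx$coef)^2, wx$scales, dt, dj, time_factor, scale_octaves)
  py <- smooth_wavelet(sinv * Mod(wy$coef)^2, wx$scales, dt, dj, time_factor, scale_octaves)
  cxy <- wx$coef * Conj(wy$coef)
  sre <- smooth_wavelet(sinv * Re(cxy), wx$scales, dt, dj, time_factor, scale_octaves)
  sim <- smooth_wavelet(sinv * Im(cxy), wx$scales, dt, dj, time_factor, scale_octaves)
  denom <- px * py
  coh <- (sre^2 + sim^2) / pmax(denom, 1e-300)
  coh[denom <= 0] <- 0
  coh <- pmin(pmax(coh, 0), 1)
  list(coh = coh, periods = wx$periods, scales = wx$scales, coi = wx$coi)
}

#' Wavelet coherence of two series
#'
#' Time- and scale-localised squared correlation between two series on the
#' same time grid: the squared modulus of the smoothed cross-wavelet spectrum
#' normalised by the smoothed auto-spectra. Smoothing is a scale-proportional
#' boxcar in time and a fixed-width (0.6 octave) boxcar across scales, the
#' standard choice for Morlet coherence. Both series are standardized
#' internally, so the result is invariant to affine rescaling.
#'
#' @param x,y Numeric series on identical, evenly spaced time grids.
#' @param times Optional time axis (same length), stored for reporting.
#' @param dt Sampling interval (years).
#' @param dj Scale resolution in octaves.
#' @param period_range Optional `c(min, max)` periods in years.
#' @param omega0 Morlet parameter.
#' @param time_factor Width of the time smoothing window relative to scale.
#' @param scale_octaves Width of the scale smoothing window in octaves.
#' @return An object of class `wavelet_coherence_result`: `coherence`
#'   (periods x times, in `[0, 1]`), `periods`, `times`, `coi`,
#'   `inside_coi` (logical matrix), `p_values` (`NULL` until
#'   [significance()] is run) and the AR(1) coefficients of the inputs.
#' @export
coherence <- function(x, y, times = NULL, dt = 1, dj = 1 / 20,
                      period_range = NULL, omega0 = 6,
                      time_factor = 1, scale_octaves = 0.6) {
  if (length(x) != length(y)) stopf("`x` and `y` must share one time grid")
  if (!is.null(times)) {
    if (length(times) != length(x)) stopf("`times` length mismatch")
    if (length(unique(round(diff(times), 8))) > 1L)
      stopf("`times` must be evenly spaced")
  } else times <- seq_along(x) * dt
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("degenerate (constant) input series")
  core <- coherence_core(x, y, dt, dj, period_range, omega0,
                         time_factor, scale_octaves)
  inside <- outer(core$periods, core$coi, `<=`)
  structure(list(coherence = core$coh, periods = core$periods,
                 scales = core$scales, times = times, coi = core$coi,
                 inside_coi = inside, p_values = NULL,
                 x = x, y = y,
                 rho_x = ar1_coef(x), rho_y = ar1_coef(y),
                 params = list(dt = dt, dj = dj, period_range = period_range,
                               omega0 = omega0, time_factor = time_factor,
                               scale_octaves = scale_octaves),
                 n = length(x)),
            class = "wavelet_coherence_result")
}

#' @export
print.wavelet_coherence_result <- function(x, ...) {
  cat(sprintf("<wavelet_coherence_result> %d periods (%.3g--%.3g yr) x %d times%s\n",
              length(x$periods), min(x$periods), max(x$periods), length(x$times),
              if (is.null(x$p_values)) "" else ", with Monte-Carlo p-values"))
  invisible(x)
}

#' Monte-Carlo significance of wavelet coherence
#'
#' Pointwise p-values against the null of two independent red-noise series:
#' surrogate pairs with the AR(1) lag-1 coefficients fitted to each input are
#' simulated, their coherence computed with identical smoothing, and the
#' p-value at each cell is the fraction of surrogate coherences that reach
#' the observed value.
#'
#' @param result A [coherence()] result.
#' @param n_sim Number of surrogate pairs (>= 1).
#' @param surrogate `"ar1"` (default): red-noise surrogates with the fitted
#'   lag-1 coefficients; `"phase"`: Fourier phase-randomized surrogates that
#'   preserve each series' full power spectrum (better calibrated for very
#'   smooth series such as SPDs, whose sub-smoothing-scale power an AR(1)
#'   process overstates); `"white"`: white noise.
#' @param seed Optional seed.
#' @return The result with `p_values` (same shape as `coherence`) filled in.
#' @export
significance <- function(result, n_sim = 100,
                         surrogate = c("ar1", "phase", "white"),
                         seed = NULL) {
  stopifnot(inherits(result, "wavelet_coherence_result"))
  surrogate <- match.arg(surrogate)
  if (!is_scalar_number(n_sim) || n_sim < 1) stopf("`n_sim` must be >= 1")
  n_sim <- as.integer(n_sim)
  p <- result$params
  rx <- if (surrogate == "ar1") result$rho_x else 0
  ry <- if (surrogate == "ar1") result$rho_y else 0
  if (surrogate == "phase" && (is.null(result$x) || is.null(result$y)))
    stopf("phase surrogates need the original series stored in the result")
  run <- function() {
    count <- matrix(0, nrow(result$coherence), ncol(result$coherence))
    for (i in seq_len(n_sim)) {
      if (surrogate == "phase") {
        xs <- phase_surrogate(result$x)
        ys <- phase_surrogate(result$y)
      } else {
        xs <- ar1_surrogate(result$n, rx)
        ys <- ar1_surrogate(result$n, ry)
      }
      cs <- coherence_core(xs, ys, p$dt, p$dj, p$period_range, p$omega0,
                           p$time_factor, p$scale_octaves)$coh
      count <- count + (cs >= result$coherence)
    }
    count / n_sim
  }
  result$p_values <- with_seed(seed, run())
  result$n_sim <- n_sim
  result$surrogate <- surrogate
  result
}

#' Per-period fraction of significant coherence cells
#'
#' For each analysed period, the fraction of cone-of-influence-interior cells
#' whose Monte-Carlo p-value falls below `alpha`. This is the scale profile
#' used to ask at which time scales a proxy significantly tracks the truth.
#'
#' @param result A [coherence()] result with p-values (see [significance()]).
#' @param alpha Significance level (default 0.05).
#' @return A data frame with columns `period` and `fraction_significant`
#'   (NA for periods with no COI-interior cells).
#' @export
significant_scale_profile <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "wavelet_coherence_result"))
  if (is.null(result$p_values)) stopf("run significance() first")
  sig <- result$p_values < alpha
  frac <- vapply(seq_along(result$periods), function(j) {
    inside <- result$inside_coi[j, ]
    if (!any(inside)) return(NA_real_)
    mean(sig[j, inside])
  }, numeric(1))
  data.frame(period = result$periods, fraction_significant = frac)
}

#' Period with the largest fraction of significant cells
#'
#' When several periods tie for the maximum (the profile typically saturates
#' over a plateau of scales around a shared feature), the geometric centre of
#' the maximal plateau is reported, since scales live on a logarithmic
#' ladder.
#'
#' @param result A [coherence()] result with p-values, or a profile data
#'   frame from [significant_scale_profile()].
#' @param alpha Significance level.
#' @param tie_tol Fractions within `tie_tol` of the maximum count as tied.
#' @return The period (years) maximising [significant_scale_profile()].
#' @export
peak_significant_period <- function(result, alpha = 0.05, tie_tol = 1e-9) {
  prof <- if (is.data.frame(result)) result
          else significant_scale_profile(result, alpha)
  ok <- !is.na(prof$fraction_significant)
  if (!any(ok)) return(NA_real_)
  f <- prof$fraction_significant[ok]; p <- prof$period[ok]
  top <- f >= max(f) - tie_tol
  exp(mean(log(p[top])))
}

#' Plot a wavelet coherence matrix
#'
#' Image of coherence over time and log2 period with the cone of influence
#' overlaid; cells significant at `alpha` are stippled when p-values exist.
#'
#' @param x A [coherence()] result.
#' @param alpha Significance level for stippling.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.wavelet_coherence_result <- function(x, alpha = 0.05, ...) {
  graphics::image(x$times, log2(x$periods), t(x$coherence),
                  xlab = "time", ylab = "log2 period (yr)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::lines(x$times, log2(pmax(x$coi, min(x$periods))), lwd = 2)
  if (!is.null(x$p_values)) {
    idx <- which(x$p_values < alpha & x$inside_coi, arr.ind = TRUE)
    if (nrow(idx) > 2000L) idx <- idx[seq(1L, nrow(idx), length.out = 2000L), ]
    graphics::points(x$times[idx[, 2L]], log2(x$periods[idx[, 1L]]),
                     pch = ".", col = "white")
  }
  invisible(x)
}
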