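# regenerates inst/extdata/synthetic_calcurve.14c (a purely synthetic,
# IntCal-dialect calibration-curve fixture; NOT real calibration data)
library(spdproxy)
cv <- make_synthetic_curve(4800, 11100, step = 5, seed = 20260909)
n <- length(cv$cal_bp)
lines <- c(
  "# synthetic_calcurve.14c — SYNTHETIC calibration-curve fixture",
  "# identity mapping plus smooth autocorrelated wiggles (sd 25 14C yr);",
  "# generated by tools/make_fixture_curve.R; no real calibration data.",
  "# CAL BP, 14C age, Error, Delta 14C, Sigma Delta 14C",
  sprintf("%d,%.1f,%.1f,%.1f,%.1f", rev(cv$cal_bp), rev(cv$c14_age),
          rev(cv$curve_error), rep(0, n), rep(0, n)))
writeLines(lines, "inst/extdata/synthetic_calcurve.14c")
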