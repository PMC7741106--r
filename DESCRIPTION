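Package: spdproxy
Title: Simulated Population Dynamics and Radiocarbon Summed Probability Proxies
Version: 0.1.0
Authors@R:
    person("spdproxy", "developers", email = "spdproxy@example.org",
           role = c("aut", "cre"))
Description: Simulates density-dependent hunter-gatherer population dynamics
    (consumer-resource limit cycles controlled by environmental productivity,
    stochastic catastrophe models, and synthetic historical tax-record series),
    forward-models them into summed probability distributions (SPDs) of
    radiocarbon dates via calibration-curve back-calibration with truncated-
    normal laboratory errors, and quantifies which time scales of the true
    dynamics the SPD proxy recovers, using exponential and growth-phase
    growth-rate estimators and Morlet wavelet coherence with Monte-Carlo
    significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
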