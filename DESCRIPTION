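Package: erknoise
Title: Dissecting Intrinsic and Extrinsic Noise in MEK-ERK Signaling Dynamics
Version: 0.1.0
Authors@R: person("erknoise", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical framework for attributing cell-to-cell variability in
    the MEK-ERK signaling module to intrinsic (reaction stochasticity) or
    extrinsic (cell-to-cell parameter heterogeneity) noise, from cross-sectional
    quantitative-image-cytometry-style single-cell snapshots. Provides the
    distributive dual-phosphorylation mechanistic model and a processive
    alternative, deterministic and exact-stochastic (Gillespie) simulation, the
    linear noise approximation for intrinsic-noise likelihoods, log-normal
    parameter populations propagated with the unscented transform for
    extrinsic-noise likelihoods, a likelihood-tempered sequential Monte Carlo
    sampler with model-evidence estimation and Bayes-factor model ranking,
    variance decomposition by parameter group, input-variability (lambda) scans,
    and kernel-density mutual-information estimation between phospho-MEK and
    phospho-ERK.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
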