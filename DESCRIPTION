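Package: leafquanta
Title: Leaf-Level Energy Partitioning from Steady-State Chlorophyll Fluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for partitioning the fate of photons absorbed by photosystem II
    from steady-state pulse-amplitude-modulated (PAM) chlorophyll fluorescence
    measurements collected along vertical profiles of structurally complex forest
    canopies. Computes the lake-model regulatory state (qL, NPQt) and the quantum
    yields of photochemistry, regulated heat dissipation and nonregulated losses
    from raw fluorescence parameters; provides quality-control filtering, canopy
    stratification with nonparametric strata comparisons and 1-m vertical
    profiles, mixed-model and beta-likelihood additive-model inference of
    environmental drivers with variance and deviance partitioning, and
    derivative-based breakpoint detection of the relationship between
    nonregulated losses and photochemical yield, classifying irradiance regimes
    into photochemical-quenching-limited, nonphotochemical-quenching-limited and
    high-stress phases. A seeded synthetic canopy-campaign generator reproduces
    the sampling design and qualitative physiology the analyses assume, so the
    full pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
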