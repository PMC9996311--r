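Package: rheoSPT
Title: Passive Microrheology from Single-Particle Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for passive-microrheology analysis of single-particle
    tracking experiments in living cells: simulation of Brownian and
    subdiffusive (fractional Brownian motion) tracer trajectories with
    localization noise, rendering of synthetic fluorescence movies, spot
    detection and frame-to-frame linking, per-trajectory time-averaged
    mean-squared displacement, effective diffusion coefficients at a fixed
    short timescale, anomalous diffusion exponents, and condition-level
    comparison statistics (median fold changes with replicate-paired
    t-tests and particle-intensity distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tiff,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
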