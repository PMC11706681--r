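Package: mitodyn
Title: Spatiotemporal Dynamics of Mitotic Events in Growing and Regenerating Root Tips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of spatiotemporal cell-division (mitotic)
    event records from long-term time-lapse imaging of plant root tips.
    Provides per-frame event counting, burst detection against a
    mean-plus-one-standard-deviation threshold, comparison of burst-size
    distributions to mode-matched Poisson nulls, periodogram (power spectral
    density) analysis of event-count time series, density-based (DBSCAN)
    spatial clustering of 3D event positions with a geometry-derived
    neighbourhood radius, pairwise cluster centre-of-mass distances, and
    condition-by-time-bin two-sample Kolmogorov-Smirnov comparisons.
    Includes a synthetic-data generator (Poisson baseline with burst
    episodes, optional sinusoidal modulation, and Thomas-process spatial
    clustering) emulating intact versus regenerating root studies, so every
    analysis stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
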