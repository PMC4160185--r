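Package: bowcoord
Title: Coordination Analysis of Fast Repetitive Violin-Bowing Patterns
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of intralimb coordination in fast
    repetitive violin-bowing patterns. Provides a generative sinusoidal
    model of bow velocity and bow inclination with a finite string-crossing
    band, zero-phase Butterworth preprocessing, Hilbert-transform and
    time-domain estimators of relative phase and normalized string-crossing
    range, per-bow-change feature extraction, coordination-space geometry
    (boundary curves, coverage ellipses), and the two-step per-condition
    aggregation used for movement-stability statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
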