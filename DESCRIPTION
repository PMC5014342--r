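Package: solegait
Title: Insole Gait Analysis, Soil-Type Differentiation and Vibrotactile
    Cueing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analyse recordings from sensor-instrumented insoles
    (tri-axial accelerometer plus force-sensitive resistors).  Detects
    heel-strike windows, applies a zero-pad/Hamming/Savitzky-Golay
    preprocessing chain, and differentiates soil types from the spectral
    centroid of the strike vibration together with time-domain statistics
    combined into an optimised weighted level.  Segments Timed Up and Go
    (TUG) trials into their phases, derives cadence, stride length and
    walking speed from step events, and scores a risk-of-falling index
    from gait-variability coefficients.  Schedules rhythmic vibrotactile
    cues at 10% above baseline cadence.  A synthetic signal generator with
    known ground truth stands in for insole hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
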