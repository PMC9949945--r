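Package: snorevol
Title: Calibration-Free Tidal Volume Level Estimation from Sleep Respiratory Sounds
Version: 0.1.0
Authors@R:
    person("snorevol", "developers", email = "snorevol@example.org", role = c("aut", "cre"))
Description: Estimates qualitative tidal volume levels (high/medium/low) per
    one-minute clip of tracheal respiratory sound without any per-subject
    calibration. Clips are clustered into snoring / normal breathing /
    uncertain with agglomerative hierarchical clustering on frame-averaged
    Mel-frequency cepstral coefficients; snoring clips are split into simple
    and apneic snoring by K-means on linear-predictive (LPC) formant
    statistics (standard deviation of F1 and of the F1 interval); an explicit
    rule table converts the maximum breathing pause interval and the elapsed
    simple-snoring time into a tidal level, evaluated against per-minute
    lowest nocturnal oxygen saturation (LoO2) levels from a 1 Hz SpO2 trace.
    Includes a deterministic synthetic generator of labelled tracheal-sound
    scenarios with consistent SpO2 traces so the whole pipeline is testable
    without clinical recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
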