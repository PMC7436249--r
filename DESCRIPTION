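Package: radvital
Title: Vital-Sign Extraction from Continuous-Wave Doppler Radar During Body Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers respiration and heartbeat rates from quadrature (I/Q)
    baseband recordings of a single continuous-wave Doppler radar, including
    recordings taken while the subject undergoes large-scale, fast body
    movement. Implements extended differentiate-and-cross-multiply (DACM)
    phase demodulation, random-body-movement cancellation by polynomial
    fitting combined with least-mean-square adaptive noise cancellation,
    a cosine-projection (N-DCT) spectral estimator with band-limited peak
    picking, and direction-based segmentation of back-and-forth motion.
    A synthetic signal generator reproduces the chest-wall plus body-motion
    model used to validate the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
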