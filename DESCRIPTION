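Package: rollscr
Title: Rolling-Window Spatially Explicit Capture-Recapture Density Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood closed-population spatially explicit
    capture-recapture (SCR) for proximity detectors (camera traps) with a
    half-normal detection function and a discretized habitat mask, applied
    over rolling windows of a long-term daily detection record. Includes a
    synthetic-data generator for camera-grid surveys of wide-ranging
    carnivores, 100% minimum convex polygon home ranges from GPS tracks with
    the circular home-range transform between sigma and area, and the
    correlation/regression summaries used to relate density estimates to
    detection-process parameters and demographic structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
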