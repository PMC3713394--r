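Package: stochsig
Title: Stochastic Gamma-Plane Signatures from Wearable Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tracks non-stationary statistical signatures of accelerometer
    activity as trajectories on the (shape, scale) plane of the Gamma family.
    Magnitudes of maximal deviations from mean acceleration are chunked into
    100-reading data entries, screened for multimodality with a dip test of
    unimodality, and fitted by Gamma maximum likelihood; the acquisition-
    ordered estimates form a stochastic trajectory whose supra-threshold
    speed peaks are themselves Gamma-fitted to give a per-person signature
    and Fano factor. Cohort-level tools include power-law scatter fits,
    k = 2 city-block k-medians clustering, centroid-distance regressions,
    rank-sum tests, and a synthetic-cohort generator with ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
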