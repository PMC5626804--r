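Package: fbdsa
Title: Filter-Bank Data Space Adaptation for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete filter-bank common spatial patterns (FBCSP) pipeline for
    two-class motor-imagery EEG decoding, together with filter-bank data space
    adaptation (FB-DSA): a closed-form, per-frequency-band linear transformation
    that aligns evaluation-session EEG to a calibration session by minimizing the
    summed class-conditional Kullback-Leibler divergence between zero-mean
    Gaussian models of the band-passed signals. Includes Chebyshev Type II
    filter-bank decomposition, CSP spatial filtering, log-variance features,
    mutual-information-based feature selection, linear discriminant analysis,
    an adaptive trial-by-trial evaluation protocol with a bounded buffer of
    recent labeled trials, chance-level cross-validation screening, covariance
    disparity diagnostics, and a synthetic two-session EEG generator with a
    controllable between-session linear mixing perturbation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo:
    Rcpp
Config/testthat/edition: 3
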