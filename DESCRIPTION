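Package: accelcal
Title: Calibration of Wrist-Worn Accelerometer Physical Activity Cut Points
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibrates counts-per-minute intensity cut points for wrist-worn
    accelerometers in young children against a hip-worn reference. Provides a
    synthetic generator for paired hip/wrist epoch-level vector-magnitude
    count data, epoch preprocessing (vector magnitude, epoch reintegration,
    Choi non-wear detection, hip/wrist alignment, participant exclusion),
    hip-reference labelling with the Butte preschool cut points, three
    calibration procedures (cumulative ROC threshold search, proportional-odds
    cumulative-logit region extraction, exact univariate k-means with k = 4),
    and agreement/daily-estimate evaluation (per-class sensitivity,
    specificity, Cohen kappa, daily minutes per intensity level).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    e1071,
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
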