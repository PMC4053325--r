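Package: lekscape
Title: Spatially Heterogeneous Analysis of Lek Attendance and Energy
    Development Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing spatial and temporal heterogeneity in
    greater sage-grouse lek attendance as a function of oil and gas
    well-pad density.  Provides lagged multi-scale roving-window point
    densities around leks, LOWESS detrending of periodic lek-count series
    with AICc span selection, a geographically weighted regression (GWR)
    engine with Monte Carlo tests of coefficient nonstationarity, inverse
    distance weighted significance mapping, and functional-response
    threshold estimation for sustainable development densities.  Includes
    a synthetic-data generator with known spatially varying lagged
    responses so every stage of the pipeline can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
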