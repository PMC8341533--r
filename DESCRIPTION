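Package: emmod
Title: Empirical Mode Modeling of Coupled Environmental Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for empirical mode modeling (EMM) of monthly environmental
    records: empirical mode decomposition (EMD) into intrinsic mode functions,
    Hilbert mean-period classification of modes into intra-annual and
    interannual bands, state-space reconstruction with simplex projection,
    convergent cross mapping (CCM) with a temporal exclusion radius, and
    random-phase (Ebisuzaki) surrogate significance testing of cross-map
    skill. Includes readers for multi-station CSV records with spline
    regularization to a monthly grid, synthetic-data generators that emulate
    the statistical structure of agricultural-production and lake-nutrient
    series, and a reproducible end-to-end pipeline with manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
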