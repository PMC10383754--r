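Package: softsense
Title: Raman Soft Sensors and a CHO Fed-Batch Kinetic Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric soft sensing of bioprocess variables from Raman
    spectra, together with a mechanistic cell-cycle model of fed-batch CHO
    (Chinese hamster ovary) cultivations. Provides Savitzky-Golay
    smoothing/derivative filters with exact integer coefficient tables,
    standard normal variate (SNV) normalisation, NIPALS partial least
    squares regression with cross-validated latent-variable selection,
    variable selection by VIP scores and competitive adaptive reweighted
    sampling (CARS), Monte-Carlo resampling outlier detection, a fed-batch
    ODE simulator of CHO cell-cycle kinetics with bolus feeding, particle
    swarm parameter estimation, and a synthetic-data generator that
    emulates paired Raman/reference data sets for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
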