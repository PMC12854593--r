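Package: sorsid
Title: Through-Container Identification of Preservation Fluids by Spatially Offset Raman Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-invasive classification of preservation fluids in
    sealed containers from paired zero-offset spatially offset Raman
    spectroscopy (SORS) measurements. Provides scaled-subtraction isolation of
    fluid and container signatures, polynomial baseline removal and standard
    normal variate normalization, principal component analysis with
    k-nearest-neighbour classification against a mock-fluid calibration set,
    non-negative multivariate curve resolution for container-material typing,
    residual-band detection of low-level additives, and a two-layer forward
    simulator for generating calibration sets and historic-cohort scenarios
    with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    pracma,
    class,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
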