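Package: eofill
Title: Gap Filling of Gridded Ocean-Colour Scene Time Series by
    Multi-Sensor Merging and Tiled DINEOF
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs missing data in gridded scene time series such as
    daily satellite chlorophyll-a imagery.  The pipeline has three stages:
    a per-sensor sliding-window pre-fill of small gaps, a same-day
    multi-sensor merge that ranks donor scenes by RMSE against a base
    image and adjusts seams with inverse-distance weighting, and a tiled
    DINEOF engine (iterative truncated-SVD matrix completion with
    cross-validated selection of the number of EOF modes and optional
    temporal covariance filtering).  Includes readers and writers for
    NetCDF, a record-framed GHER-dialect binary, DINEOF init files, a
    seeded synthetic multi-sensor scene generator with swath gaps and
    correlated cloud masks, and an evaluation harness for cloud-coverage
    and hyper-parameter experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
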