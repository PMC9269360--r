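Package: bloomstage
Title: Phytoplankton Bloom Stage from Chlorophyll Phenology and Pheophytin Proportions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the stage of a phytoplankton bloom at the time
    of field sampling by combining satellite-derived chlorophyll-a phenology with
    shipboard pigment measurements. Irregular station-year chlorophyll time series
    are quality-controlled, smoothed with a tricube locally weighted linear fit,
    interpolated to a daily curve, and segmented into bloom cycles whose start,
    peak, and end dates classify a sampling day as Early Bloom, Post Bloom, or No
    Bloom. Shipboard pheophytin proportions, pheophytin / (chlorophyll-a +
    pheophytin), are calibrated against the satellite stages by an exhaustive
    integer-percentage threshold scan scored with remote-sensing error matrices
    (overall accuracy, omission and commission errors). Sea-ice year
    classification (breakup-date detection, at-most-one-change changepoint,
    spring open-water rule) and Welch's t-test group comparisons of pheophytin
    proportions in high versus low ice years complete the pipeline. A synthetic
    data generator emulates cloud-thinned chlorophyll series, seasonal ice
    decline, and stage-dependent pigment profiles so the whole analysis is
    testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
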