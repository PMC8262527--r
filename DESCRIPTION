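Package: chillforce
Title: Winter Chill and Heat Forcing Assessment Under Climate Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to assess winter chilling (Chill Portions from the
    Dynamic model) and heat forcing (Growing Degree Hours) of temperate
    fruit-growing regions under baseline and scenario climates. Provides
    daily-to-hourly temperature reconstruction from daily extremes and
    latitude, thermal accumulation over fixed seasonal windows, empirical
    quantile-mapping bias correction of simulated temperatures, bilinear
    regridding, Safe Winter Chill and Safe Heat Forcing percentile
    indices, multi-model ensemble statistics, regional extraction with
    linear trends, and a synthetic weather generator with known imposed
    structure so the full pipeline can be exercised and tested without
    external gridded datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ncdf4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
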