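Package: greenlakes
Title: Catchment Greening and Nutrient Sequestration Analysis for Subarctic Lakes
Version: 0.1.0
Authors@R:
    person("Vivan", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links landscape greening to lake oligotrophication: delineates
    lake catchments from elevation rasters (depression filling, D8 routing,
    flow accumulation, outlet snapping), extracts annual maximum NDVI for
    plots and drainage areas under snow and acquisition-time filters,
    calibrates NDVI against plot-scale vegetation nutrient densities,
    computes per-lake and regional phosphorus and nitrogen sequestration
    contrasts, and provides the accompanying trend statistics (Mann-Kendall,
    Sen's slope, penalized-spline mixed smooths) and Horvitz-Thompson cover
    estimation. Includes a seeded synthetic landscape generator so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv
Config/testthat/edition: 3
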