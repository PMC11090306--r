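Package: extralimitr
Title: Detection and Mapping of Extralimital Species Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for reassessing species range limits from
    georeferenced occurrence records. Reads and cleans Darwin Core style
    occurrence tables, builds baseline minimum convex polygon (MCP) ranges from
    published marginal records and current concave-hull ranges from full
    occurrence sets, classifies records as inside, marginal, or extralimital
    against a baseline range with a spatial tolerance, scores range-map accuracy
    (sensitivity and hydrologic-unit occupancy), summarises displacement
    distances and bearings with circular statistics, and overlays extralimital
    records on managed-land units. Includes a fully specified synthetic-scenario
    generator with ground truth so every pipeline stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    dplyr,
    grDevices,
    jsonlite,
    polyclip,
    readr,
    rlang,
    spatstat.geom,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    geosphere,
    ggplot2,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
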