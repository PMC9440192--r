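Package: stscan
Title: Space-Time Scan Statistics for Prospective Suicide Cluster Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects space-time clusters of point-referenced health events
    (developed for small-area suicide mortality surveillance) with the
    discrete-Poisson cylindrical scan statistic, in both retrospective and
    prospective modes. Provides SaTScan-compatible and CSV input formats with
    small-area population denominators, conditional Monte-Carlo significance
    testing, periodic prospective surveillance replay with an alarm timeline,
    seeded synthetic-data generation with planted clusters for power and
    calibration studies, demographic breakdown tables, GeoJSON cluster-map
    export, and a command-line interface for reproducible batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
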