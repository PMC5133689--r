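Package: drivecrumb
Title: Naturalistic Driving Profiles from In-Vehicle GPS Breadcrumbs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw in-vehicle GPS "breadcrumb" fixes (30-second
    sampling) and vendor trip-activity logs into per-driver, per-month
    driving profiles with spatial components (primary locations from
    ignition-on clustering, convex-hull driving areas, mean centers,
    buffer-dissolve unique-destination counts), temporal components
    (day/dawn/dusk/night trip classification from NOAA solar events), and
    behavioral components (overspeeding, hard-braking and
    sudden-acceleration alerts). Includes schema-validating ingest and
    cleaning with a removal audit, trip reconstruction from ignition
    events, nearest-street-segment annotation, and a ground-truthed
    synthetic driver simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    geosphere,
    igraph,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
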