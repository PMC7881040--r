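Package: vegcarry
Title: Vegetation Growth Carryover Analysis for Seasonal and Interannual Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify vegetation growth carryover (VGC), the legacy of
    a preceding season's or year's vegetation state on subsequent growth, from
    gridded vegetation-index fields, site productivity records, and tree-ring
    chronologies. Provides phenology-based delineation of early, peak, and late
    growing seasons from the climatological seasonal cycle; climate-controlled
    partial-correlation profiles of seasonal and interannual memory; linear
    trend attribution that decomposes multi-year greening trends into
    carryover, lagged-climate, and concurrent-climate contributions;
    cubic-smoothing-spline standardization and robust biweight chronology
    building for ring-width series; per-cell dominant-driver classification
    with area-fraction summaries; and a recursive path model of
    vegetation-climate-soil coupling. Includes synthetic-data generators with
    recorded ground truth for all estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
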