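Package: ecoprofit
Title: Economic-Ecological Trade-Off Analysis for Smallholder Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify trade-offs between agricultural profit and
    biodiversity or ecosystem functioning in plot-based land-use studies.
    Estimates plot-level profits from household yield-profit regressions
    with heteroscedastic residual variance, corrects smooth
    response-profit regressions for the resulting measurement error via
    simulation-extrapolation (SIMEX) over penalized splines, computes
    threshold-based multidiversity and multifunctionality indices, and
    searches for profit-constrained optimal landscape compositions with
    a binary genetic algorithm backed by an exact small-instance
    enumerator. A seeded synthetic-data generator emulating a
    four-system, two-landscape, 32-plot design makes the full pipeline
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
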