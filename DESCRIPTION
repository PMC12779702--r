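Package: firestruct
Title: Post-Fire Structural Recovery Groups from Spectral Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape-scale analysis of post-fire forest structural
    recovery in dry sub-boreal conifer systems. Derives spectral-recovery
    metrics (regrowth magnitude, median slope, year-5 value for seven Landsat
    indices, plus dNBR burn severity) from annual index time series, screens
    pixels with a BARC-A severity threshold, clusters the standardized
    22-metric vectors with seeded k-means++, merges clusters into structural
    recovery groups by PERMANOVA against a space-for-time structure
    chronosequence, computes terrain, fire-impact, climate-normal and
    climate-anomaly recovery drivers, and attributes groups to drivers with a
    tiered random-forest procedure (per-category forests, consolidated global
    forest, Boruta shadow-feature importance, partial dependence). Includes a
    fully synthetic landscape generator with planted ground truth so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan,
    optparse
Config/testthat/edition: 3
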