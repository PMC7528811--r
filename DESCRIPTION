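Package: occfiltr
Title: Quality Filtering of Species Occurrence Records with Downstream
    Richness and Red-List Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flags potentially problematic geo-referenced species occurrence
    records using thirteen meta-data and gazetteer-based quality tests, and
    classifies flagged records as erroneous (likely wrong coordinates) or
    unfit (too imprecise or unsuitable for most downstream analyses).
    Includes equal-area (Behrmann) gridded species richness, automated
    preliminary IUCN Criterion B conservation assessment (extent of
    occurrence, area of occupancy, number of locations), comparison of
    raw-versus-filtered assessments against reference categories, and a
    synthetic-data generator that plants labelled contamination into a toy
    gazetteer world so the whole pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
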