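Package: sampleflow
Title: Process, Flag, and Report on Ecological Field-Sampling and
    Specimen-Isolation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to clean, flag, join, geospatially annotate, and report on
    ecological field-sampling and specimen-isolation data exported from a
    mobile geographic data-collection platform. Barcoded collections
    (C-labels) are linked to specimens isolated in the laboratory (S-labels)
    and to their molecular-barcode species identifications. The package
    standardizes temperatures, times, and labels, flags anomalies such as
    suspected Fahrenheit readings and stuck temperature probes, selects the
    most precise photo GPS fix per collection, annotates sampling sites with
    user-supplied polygon features, processes collection photographs into
    renamed copies and thumbnails, and generates a self-contained HTML
    collection report with a pin map and per-species environmental box
    plots. A seeded synthetic-project generator produces complete example
    projects with a ground-truth anomaly manifest for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jpeg,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    sp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
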