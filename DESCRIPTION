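Package: rsvicast
Title: Nowcasting Cancer Incidence from Relative Search Volume Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Short-term nowcasting of yearly cancer incidence counts from
    Google Trends relative search volume index (RSVI) ratios. A region's
    predicted count for year t is its count in year t-1 multiplied by
    RSVI(t)/RSVI(t-1). The package provides the one-step predictor,
    percentage-error validation against reported actuals, chained multi-year
    projection for years without reported data, error summaries and paired
    model comparison, readers for tidy incidence/RSVI tables and Google
    Trends 'multiTimeline' exports, packaged state- and country-level
    validation tables, a seeded synthetic generator of coupled
    incidence/search series for property testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    datasets,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
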