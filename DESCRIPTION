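Package: cohortviz
Title: Animated Visualization of HIV Cohort Data from HICDEP Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Configuration-driven pipeline for building animated visualizations
    of HIV cohort data stored as HICDEP-style comma-separated tables. Reads and
    validates flat-file cohorts, parses CSV plot-specification files with a safe
    expression mini-language for subsetting and indicator definitions, derives
    per-subject timelines (start dates, truncated follow-up, event-attributed
    values, baseline measures) and country-year aggregates, and renders three
    classes of animated graphics as PNG frame sequences with an HTML scrubber
    viewer: longitudinal scatter with LOESS curves, marginal densities and
    Kaplan-Meier event-probability panes; per-period bubble plots of paired
    indicator proportions with mosaic margins or darkening multi-period trails;
    and temporal choropleth maps of country-level proportions. Includes a
    deterministic synthetic-cohort generator so the full pipeline is testable
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
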