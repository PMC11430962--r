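Package: fcaccess
Title: Floating Catchment Area Accessibility Indices for Health Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes small-area availability and accessibility indices for
    health-service provision using a modified-Huff, variable-catchment,
    three-step floating catchment area model with calibrated travel-time
    decay. Given demand zones, capacitated providers and a zone-by-provider
    travel-time matrix, the model allocates demand to providers by Huff
    probabilities over each zone's Q nearest reachable providers, forms
    provider supply-to-demand ratios, and returns a Spatial Density Index
    (availability, capacity units per 1000 residents) and a Spatial
    Accessibility Index (decay-weighted accessibility score) per zone.
    Includes a synthetic-region generator for testing, a what-if scenario
    engine for provider openings and closures, stratified quartile
    summaries and aggregation to coarser geographies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
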