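Package: arscape
Title: Residence-Time Analysis of Animal Movement Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring detailed space use from relocation data with
    residence times. Computes first-passage and residence times along a
    trajectory, builds variance-scale curves (variance of log residence time,
    or its coefficient of variation, against circle radius) and detects their
    peaks to identify the distinct spatial scales at which an animal performs
    area-restricted search (ARS). At a chosen scale, a four-step algorithm
    identifies spatially distinct revisited ARS places and summarises each by
    its mean visit duration and number of revisits. Includes a biased
    correlated random walk foraging simulator (scattered, patchy and
    hierarchical resource maps; simple search, simple ARS and hierarchical
    ARS strategies) with ground-truth logging for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
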