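Package: holctools
Title: Linking Historical HOLC Redlining Grades to Present-Day Census Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring present-day census tract exposure to 1930s
    Home Owners' Loan Corporation (HOLC) neighborhood risk grades
    ("redlining" maps). Computes per-tract grade coverage compositions from
    polygon overlay, enumerates candidate tract classification schemes
    (binned and rank-ordered, with or without unrated area as a pseudo-grade),
    scores every scheme by five-fold cross-validated prediction error over
    multiple tract outcomes, meta-analyzes which scheme features drive
    predictive validity, and derives predictively optimal, parsimonious and
    collapsed ten-class classifications for applied neighborhood health
    research. Includes a synthetic-data generator (compositional coverages
    plus correlated outcomes with a monotone grade gradient) so the whole
    pipeline is testable without external census or health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    polyclip,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
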