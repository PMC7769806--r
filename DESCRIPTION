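Package: equidea
Title: Equity and Efficiency Analysis of Regional Health-Resource Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the equity and the productive efficiency of
    regional health-resource allocation from province-by-year panels of inputs
    (institutions, beds, health staff) and outputs (outpatient visits,
    discharged patients). Implements Lorenz curves, the Gini coefficient (both
    the Hoover/Robin-Hood form and the Lorenz-trapezoid form), the Theil index
    with its within-/between-group decomposition and contribution rates,
    output-oriented radial data envelopment analysis (DEA) under constant and
    variable returns to scale with two-stage slack maximisation and
    returns-to-scale classification, and the adjacent-period Malmquist
    productivity index with the Fare-Grosskopf-Norris-Zhang four-way
    decomposition. A synthetic-data module generates grouped panels and
    production frontiers with known inefficiencies so the whole pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    boot,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
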