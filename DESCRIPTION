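Package: villimorph
Title: Villous Morphometry, Trial Simulation and Power Analysis for
    Environmental Enteropathy Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative small-intestinal villous morphometry and
    for the statistical machinery of randomised trials that use it.
    Generates synthetic haematoxylin-and-eosin-like jejunal cross sections
    with exact geometric ground truth; measures villous height, crypt depth,
    villous width, and threshold-segmented villous perimeter and
    cross-sectional area normalised per 100 micrometres of muscularis
    mucosae; simulates masked 1:1:1:1 randomised cohorts with HIV strata,
    correlated morphometric measures and biopsy attrition; routes group
    comparisons by Shapiro-Wilk normality to t or rank-based tests with
    Hodges-Lehmann intervals; and performs exact two-sample t-test power and
    sample-size calculations on the non-central t distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
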