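Package: ltrmnm
Title: Lifetime Risk of Maternal Near Miss and Severe Maternal Outcome
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the lifetime risk of maternal near miss (LTR-MNM),
    the lifetime risk of maternal death (LTR-MD) and the lifetime risk of
    severe maternal outcome (LTR-SMO) for a synthetic period cohort of
    women surviving to age 15, from abridged female life tables,
    age-specific fertility schedules and maternal near miss (or maternal
    death) ratios.  Supports both the age-disaggregated estimator and the
    summary-estimate shortcut via the net reproduction rate and sex ratio
    at birth, simulation of plausible age patterns of the near miss ratio
    constrained to a fixed aggregate level, stillbirth and
    institutional-delivery adjustments, and exact-Poisson / Monte Carlo
    uncertainty intervals.  Ships the Namibia 2019 worked example as an
    embedded fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
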