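Package: pdisim
Title: Putative Dialysis Initiation Times for Conservative Management Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the putative dialysis initiation (PDI) time of
    advanced chronic kidney disease patients managed conservatively, and for
    validating that estimation by Monte Carlo simulation. Longitudinal eGFR
    trajectories are simulated from a linear mixed effects model with staggered
    recruitment and irregular visit schedules; each subject's threshold-crossing
    (PDI) day is estimated by per-subject least squares and by mixed-model
    subject-specific (BLUP) prediction; estimated PDI days are then used as the
    start of follow-up to construct survival datasets, whose Kaplan-Meier and
    reverse Kaplan-Meier summaries are compared with the generating truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
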