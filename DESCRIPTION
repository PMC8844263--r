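Package: mirdose
Title: MIRD-Schema Internal Dosimetry for PET Radiopharmaceuticals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for first-in-humans internal
    radiation dosimetry of F-18 labelled PET tracers: organ time-activity
    curves are normalized, fitted with mono-exponential biologic washout,
    and integrated (with explicit physical decay) into residence times;
    urinary excretion is fitted from timed urine collections and converted
    to a bladder-content residence time with the dynamic voiding model;
    organ absorbed doses follow the MIRD schema on a reference adult
    phantom extended with salivary and lacrimal glands (sphere-model
    self-dose), and the effective dose uses ICRP-60 tissue weighting with
    configurable remainder handling. A seeded synthetic-cohort generator
    calibrated to published whole-body biodistribution data makes every
    stage testable without subject-level study data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
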