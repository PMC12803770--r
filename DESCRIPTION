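Package: hbdefer
Title: Blood Donor Haemoglobin Deferral Based on Historical Mean Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating an alternative blood-donor low-haemoglobin
    deferral policy that considers a donor's historical mean haemoglobin and
    the measurement variability of the screening method, in the spirit of a
    laboratory control chart. Provides estimation of haemoglobin measurement
    variability from successive within-donor differences, per-visit
    eligibility assessment with mean-based (reason A) and low-outlier
    (reason B) deferrals, retrospective re-assessment of complete visit
    datasets with deferral-rate and donation-change accounting, parameter
    sweeps over the policy's confidence levels, and a synthetic donor-career
    generator for method evaluation when registry data are unavailable.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
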