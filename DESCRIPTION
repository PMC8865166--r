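Package: drivecr
Title: Event-Locked Cardiac and Speed Responses to Driving Hazards
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for event-related cardiac responses and speed
    adaptation during simulated driving. Turns raw electrocardiogram and
    speed traces with cue/event markers into baseline-referenced change
    epochs on a 0.5 s grid, summarises them with signed areas under the
    curve, and tests them with within-subject repeated-measures ANOVAs
    (Greenhouse-Geisser corrected), Bonferroni post hocs, orthogonal
    polynomial trend contrasts for the biphasic deceleration-acceleration
    anticipation signature, and paired comparisons between perceived-stress
    groups. Includes a seedable synthetic driving-session simulator with a
    ground-truth manifest so every stage is testable without access to raw
    participant data.
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
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
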