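Package: caninestep
Title: Collar-Accelerometer Pedometry for Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Step counting and distance estimation for dogs from a
    collar-mounted tri-axial accelerometer. Corrects collar rotation by
    solving a sagittal-plane restriction of Wahba's problem against the
    gravity vector, detects steps as falling-flank zero-crossings of the
    dorso-ventral acceleration with an adaptive zero-line, gates candidates
    by an allometric stride-frequency band, rejects shuffles with a
    candidate-window rule, and converts per-step "bounce" (A_max - A_min)
    to step length through an inverted-pendulum model. Includes GPS walk
    segmentation with haversine path length, validation statistics
    (swing-phase matching, positive predictive value, Bland-Altman
    agreement, mean similarity), a synthetic gait simulator with exact
    ground truth, and the published study tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
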