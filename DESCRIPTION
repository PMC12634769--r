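Package: batbouts
Title: Torpor Bout Segmentation and Nightly Weather Covariates from
    Skin-Temperature Biologging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing winter torpor in cave-roosting bats from
    temperature-sensitive radio-transmitter logs. Fits per-transmitter cubic
    pulse-interval calibrations, decodes pulse logs into regular-grid skin
    temperature traces, segments traces into torpor bouts, arousal events and
    normothermia bouts using a body-mass and roost-temperature based onset
    threshold, computes sunset-to-sunrise night windows (NOAA solar equations)
    and nightly weather covariates (mean air temperature, absolute humidity,
    wind, total rain, overnight barometric-pressure change), runs circular
    statistics (Rayleigh test, von Mises kernel mode) on arousal timing,
    summarises bout durations and body-mass change, and exports analysis-ready
    model frames for torpor bout duration, nightly arousal probability and
    normothermia duration. A ground-truthed synthetic biologging generator
    emulates weather, torpor-arousal schedules, transmitter encoding with
    dropouts, and site- and sex-structured body-mass trajectories, so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
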