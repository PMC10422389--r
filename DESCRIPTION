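Package: footkinetics
Title: Multisegment Foot Joint Kinetics from Plantar Pressure Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three-dimensional external joint moments at the ankle,
    midtarsal and metatarsophalangeal joints of the shod foot from synchronized
    marker trajectories and plantar-pressure recordings (ground pressure
    platform and in-shoe instrumented insole). Pressure frames are converted to
    segmented normal contact forces by assigning sensing cells to foot segments
    from the anteroposterior location of joint centers; insole cells are
    registered into the laboratory frame by matching device centers of pressure
    shortly after initial contact. Moment curves are time-normalized to the
    stance phase, body-weight normalized, summarized by peak magnitude and
    timing parameters, and compared across devices with two-way mixed-effects
    intraclass correlation coefficients. A synthetic gait-trial generator
    samples both sensor grids from one continuous pressure field with exact
    ground truth, so every pipeline stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
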