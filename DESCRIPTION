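Package: tibload
Title: Remote Tibia Bone-Load Monitoring from Pressure Insoles and Fitness Trackers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates tibia compression force from pressure-insole total force
    and center-of-pressure signals, computes minute-wise loading stimulus (LS)
    and the cumulative daily load stimulus (DLS) used in bone-remodeling
    research, and trains generic (leave-one-participant-out) and
    participant-calibrated LASSO models that estimate LS from wrist fitness
    tracker minute metrics. Includes a sliding-window wear-time simulation that
    characterizes DLS error as a function of daily insole coverage, and a
    synthetic-cohort generator producing day-long insole and wrist streams with
    ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
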