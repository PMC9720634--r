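Package: srmsim
Title: Simulation Engine for Adaptive Spatial-Release-from-Masking Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully simulatable engine for adaptive spatial-release-from-masking
    (SRM) speech tasks. Implements the transformed up-down (2-down/1-up)
    staircase over either target-to-masker ratio (TMR) or masker azimuth,
    a continuous word/digit stream with a timed response window, parametric
    virtual listeners with a probit psychometric surface over (TMR, separation),
    equal-power panning on a horizontal loudspeaker ring, and the full
    protocol orchestration (co-located tracking, SRM-offset TMR, adaptive-angle
    tracking, fixed-separation validation, quiet and babble backgrounds).
    Monte-Carlo tools characterize the procedure's bias, precision, convergence
    accuracy and track duration without human subjects or audio hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
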