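Package: footclear
Title: Whole-Foot Minimum Clearance from a Foot-Mounted IMU and a
    Personalized Shoe Scan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs swing-phase trajectories of every point on a shoe
    from a single foot-mounted inertial measurement unit (IMU) combined with
    a personalized shoe-scan point cloud, and estimates instantaneous and
    minimum foot clearance (mFC). Implements zero-velocity-update (ZUPT)
    pedestrian dead reckoning with per-stride acceleration-bias and
    heel-strike impulse correction, a support-plane flat-foot tilt
    correction, floor-height estimation from stance-phase lowest points,
    late-swing lowest-point density mapping over the sole, and
    mixed-effects limits-of-agreement validation against optical motion
    capture. A built-in gait simulator with analytic clearance oracles
    makes the whole pipeline testable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
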