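Package: vswim
Title: Measurement and Modeling of Vertical Swimming Kinematics in Small Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for videographic measurement of posture and
    vertical locomotion in small swimming animals, built around the larval
    zebrafish. Provides a ground-truth simulator of vertical swimming (bout
    latents, continuous pose traces at the acquisition frame rate, and
    rendered grayscale frames), a frame-level tracker that converts image
    stacks into pose records, swim-bout and inter-bout-interval extraction
    with peak-speed alignment, the four kinematic parameter fits (bout-timing
    parabola, steering line, fin-body logistic, righting line) as classed
    model objects, and a resampling-based resolution analysis (confidence
    interval width versus sample size, and Cohen's d effect-size curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
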