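Package: autoscope
Title: Queue-Driven Smart Microscopy Acquisition Engine with a Simulated
    STED/Confocal Microscope
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A hardware-agnostic automation engine for smart (feedback)
    microscopy. Experiments are expressed as a dynamic priority queue of
    acquisition tasks; after every acquisition, per-hierarchy-level callbacks
    built from small composable building blocks analyse the new image and
    enqueue further tasks (overview-detail imaging, pre-scan gating,
    on-the-fly tile stitching with phase-correlation registration, software
    autofocus, pole-tile selective imaging, reactive timelapse). A simulated
    confocal/STED microscope with Gaussian optics, Poisson and read noise,
    dose-dependent photobleaching, stage drift, slide tilt and a simulated
    acquisition clock implements the same microscope interface, so complete
    pipelines run and are testable entirely at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
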