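Package: glareDrop
Title: Label-Free Particle Detection in Free-Falling Nanoliter Droplets
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects micrometer-scale particles (polymer beads, multicellular
    spheroids) inside free-falling nanoliter droplets from single camera
    frames. Implements three single-frame detectors -- white pixel count
    (WPC), glare-point contour count (CC), and droplet image similarity
    (DIS) -- together with their empty-droplet calibration procedures, batch
    evaluation with per-run accuracy reporting, and a seeded synthetic
    droplet-image generator covering both glare-point projection and diffuse
    anterior illumination, including a geometric-optics glare-point
    placement model based on Snell refraction and single internal
    reflection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
biocViews: Software, Visualization, CellBasedAssays
Config/testthat/edition: 3
RoxygenNote: 7.3.3
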