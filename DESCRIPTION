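Package: turnsfm
Title: Turntable Photogrammetry for All-Around 3D Plant Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for designing and simulating multi-camera turntable
    photogrammetry studios for non-contact 3D plant phenotyping. Provides the
    resolution and camera-placement calculations used to lay out a studio
    (planar and depth resolution from focal length, pixel pitch, working
    distance, tilt and stereo baseline angle), a synthetic studio simulator
    with a coded-target measurement bar and parametric plant, circular
    coded-target detection with subpixel centers, self-calibrating bundle
    adjustment over intrinsics, per-step poses and 3D structure, metric scale
    recovery from known inter-target distances, background-mask filtering,
    per-camera point-cloud construction and merging, and length-accuracy
    evaluation against reference distances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    jsonlite,
    png,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
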