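Package: brainplane
Title: Semi-Manual Atlas Alignment, Registration and Cell Mapping for
    Coronal Brain Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping cells detected in coronal light-sheet
    image stacks of cleared mouse brains onto a reference atlas.
    Implements anchor-based anterior-posterior alignment through a
    coarse-to-fine "choice game" and midpoint checks, piecewise
    interpolation of anterior-posterior coordinates with morph-ratio
    profiling, thin-plate-spline plate registration from contour
    correspondence points, per-plane blob segmentation with 3D
    consolidation of duplicate detections, forward warping of cells
    into atlas plate coordinates, hierarchical region-count tables and
    sunburst exports, and a synthetic phantom generator providing
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
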