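Package: acinostereo
Title: Design-Based Stereology of Pulmonary Acini from 3D Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for morphometric analysis of individual pulmonary acini in
    high-resolution 3D image stacks across postnatal lung development.
    Generates synthetic acinar phantoms with exact voxel-level ground truth,
    extracts single acini by threshold region growing bounded by disk-shaped
    segmentation stoppers, estimates acinar volume by Cavalieri point counting
    and alveolar number by physical-disector counting of entrance-ring events
    on systematic uniform random section sets, applies shrinkage correction,
    and aggregates per-acinus records into per-animal and per-day summaries
    (coefficients of variation, size-quintile ratios, normalized volume
    distributions, acini per lung, total alveoli, sphere-equivalent alveolar
    diameters) with rank-based group comparisons under Sidak correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
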