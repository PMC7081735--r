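Package: octseg
Title: Automated Retinal Layer Segmentation and Thickness Quantification
    for Rodent OCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated segmentation of rodent spectral-domain optical
    coherence tomography (SD-OCT) B-scans. The sclera is localized as the
    brightest structure on a coarsely Gaussian-smoothed image, the outer
    retinal boundary as the first valley of the axial intensity slope above
    the sclera, and the inner retinal boundary as the strongest slope peak
    more than a minimum offset above the outer boundary. Per-A-scan retinal
    thicknesses are aggregated to B-scan statistics, noisy B-scans are
    discarded by a coefficient-of-variation rule, and volume means are
    computed as inverse-SD weighted averages with a standard error among
    B-scans. Includes a synthetic OCT phantom generator with speckle noise
    and exact ground-truth boundaries, readers and writers for image-stack
    volumes with physical-spacing sidecars, group comparison via one-way
    ANOVA with Bonferroni post hoc tests, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
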