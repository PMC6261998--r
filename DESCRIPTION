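Package: orientspim
Title: Depth-Resolved Image Quality for Magnetically Oriented Light-Sheet Imaging
Version: 0.1.0
Authors@R:
    person("Imaging", "Methods Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying depth-dependent image quality in selective
    plane illumination microscopy (SPIM) stacks with a local-entropy sharpness
    statistic, and for simulating how sample orientation changes that quality.
    Includes a synthetic zebrafish-embryo phantom and SPIM image-formation
    model (illumination attenuation, depth-dependent detection blur), a
    ground-truth multi-view fusion pipeline, a comparison of single-view,
    multi-view-fused and optimally oriented ("multi-axis") acquisitions along
    the animal-vegetal axis, and a geometric model of a tetrahedral
    electromagnet array used to reorient embryos via injected
    superparamagnetic beads. Stacks are read and written as uncompressed
    multi-page TIFF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
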