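Package: retoct
Title: Retinal Layer and Microvascular Phenotyping from
    Polarization-Sensitive OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for volumetric polarization-sensitive
    optical coherence tomography (PS-OCT) of the mouse retina: RPE
    detection from the cross-polarized channel, retinal flattening and
    motion compensation, graph-shortest-path segmentation of seven
    retinal boundaries with annular thickness statistics, three-plexus
    OCT-angiography vessel density quantification with artifact removal
    and subregion SNR confidence masking, and random-intercept
    mixed-model group comparison with Satterthwaite degrees of freedom.
    Includes a synthetic phantom generator with exhaustive ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
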