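Package: longfuse
Title: Longitudinal Multimodal Fusion of Brain Connectivity and Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking longitudinal change in functional network
    connectivity (FNC) to longitudinal change in voxel-wise gray matter
    volume (GMV) via multimodal fusion. Implements construction of
    subject-by-feature change matrices (delta-FNC cells, delta-GMV voxels)
    from network time courses and volumetric maps, quality control of
    normalization masks, an asymmetric fusion arm (infomax independent
    component analysis of delta-FNC followed by voxel-wise coupling maps),
    a symmetric fusion arm (multiset canonical correlation analysis
    followed by joint ICA), loading-level statistics with
    Benjamini-Hochberg false discovery rate control, sex and score-quartile
    coupling contrasts, and a linked-source synthetic cohort generator
    with stored ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
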