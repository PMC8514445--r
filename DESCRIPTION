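Package: mesomap
Title: Registration and Segmentation of Mesoscale Cortical Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for aligning wide-field (mesoscale) cortical fluorescence
    images of the mouse dorsal cortex to a common reference atlas and back,
    segmenting the brain boundary, extracting labeled brain-region ROIs, and
    building motif-based functional maps (MBFMs) from spontaneous-activity
    movies. Registration is landmark-based (two-point similarity, three-point
    affine, least-squares multi-point affine, per-hemisphere warping, and
    piecewise-affine alignment from sensory activation peaks), with dense
    deformation-field application for externally estimated non-linear warps.
    Motif discovery uses convolutional non-negative matrix factorization;
    motifs are clustered with a shared-nearest-neighbor graph and Louvain
    community detection. A synthetic phantom generator provides ground-truth
    scenes, misaligned variants, mock landmark observations, and activity
    movies with planted motifs, so every stage of the pipeline can be
    exercised and validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    yaml,
    cluster,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
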