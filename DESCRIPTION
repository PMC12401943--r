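Package: dfsct
Title: Simulation and Weighted Cone-Beam Reconstruction for Dual-Focal-Spot CT Geometries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation study of wide z-coverage computed tomography
    geometries. Provides analytic body-phantom ray tracing, a monoenergetic
    Poisson forward projector with bowtie flux modulation, weighted cone-beam
    filtered backprojection (cosine pre-weighting, equiangular ramp filtering,
    Parker short-scan weights, cone-angle-dependent pixel-wise weighting with
    per-voxel redundancy normalization, helical per-voxel view windows, and
    dual-focal-spot merging), and image-quality metrics (ROI noise, percent
    deviations, line profiles, artifact RMSE) for comparing a dual-focal-spot
    single-detector geometry against single-source 40 mm and 140 mm detectors
    under axial half/full and helical scan protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    withr,
    tools,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
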