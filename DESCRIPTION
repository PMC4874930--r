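Package: petoss
Title: Graph-Based Just-Enough-Interaction Segmentation of Hot Lesions in PET Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiautomated segmentation of hot lesions (tumors, metabolically
    active lymph nodes) in volumetric FDG-PET scans. A spherical column graph
    is built around a user seed point, an adaptive threshold is derived from
    robust radial shell statistics, per-node costs are assembled from a
    histogram-envelope background model, and the globally optimal closed
    boundary surface is extracted by a minimum-cut optimal-surface
    transformation. Includes just-enough-interaction global and local
    refinement with undo, label avoidance, watershed-based lesion splitting,
    a necrotic-lesion mode, voxelization to label maps, synthetic PET lesion
    phantoms with Gaussian point-spread blur, and Dice agreement metrics.
    Volumes are read and written in NIfTI-1 and NRRD formats.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
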