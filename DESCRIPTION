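Package: fetalmorpho
Title: Longitudinal Fetal Brain Surface Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Longitudinal morphometry of the fetal brain from segmentation
    label volumes. Extracts closed triangulated surfaces of the unmyelinated
    white matter, ventricles and cerebellum from isotropic label volumes,
    computes structure volume, surface area and the global shape parameter
    (volume/surface area), estimates per-vertex principal curvatures and the
    derived gyrification markers (curvedness and shape index), establishes
    intra-subject longitudinal vertex correspondence by joint spectral
    matching on graph-Laplacian eigenmodes, parcellates the cortical surface
    into lobes and hemispheres, and runs nonparametric three-period
    weekly-rate-of-change group statistics. Includes a synthetic longitudinal
    cohort generator with full ground truth so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    RNifti,
    igraph,
    nortest,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
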