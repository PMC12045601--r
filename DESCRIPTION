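Package: prolifatlas
Title: Atlas-Based Quantification of 3D Cell Proliferation and Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating three-dimensional patterns of cell
    proliferation to tissue morphology in light-sheet volumes of developing
    embryos. Provides volumetric data types and NIfTI/TIFF I/O, a synthetic
    phantom-cohort generator with known ground-truth growth fields,
    nucleus/proliferation map post-processing and axis profiling, landmark
    and groupwise affine registration with majority-vote tissue atlases,
    demons-style deformable registration with Jacobian-determinant
    voxel-based morphometry, normalized proliferation heatmaps,
    differential-volume shape-change correlation, random-mask enrichment
    nulls, generalized Procrustes analysis, two-block partial least squares
    with permutation inference, and linear-SVM genotype classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    e1071,
    tibble,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
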