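Package: fmorph
Title: Landmark-Free Geometric Morphometrics with Functional Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated, landmark-free geometric-morphometrics pipeline for
    collections of bone surface meshes. Estimates functional correspondences
    between triangular meshes from spectral (Laplace-Beltrami) descriptors,
    refines them jointly over a collection with Limit-Shape-based Consistent
    ZoomOut, and characterises shape variation as area-based and conformal
    latent shape-space differences (LSSDs), with weighted distinctive
    functions that localise between-group variability directly on the bone
    surface. Includes mesh I/O and preprocessing (unit-area normalisation,
    resampling, rigid prealignment), an unsupervised Siamese descriptor
    learning module, downstream shape-space statistics (PCA, distance-matrix
    correlation, cross-validated group classification, landmark-transfer
    validation), and seeded synthetic mesh-collection generators with known
    ground-truth correspondences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    MASS,
    e1071,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
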