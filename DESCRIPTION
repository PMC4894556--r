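Package: vesselssm
Title: Landmark-Free Statistical Shape Modelling of Vascular Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical shape modelling of tubular vascular anatomies
    (aortic arches in particular) without manual landmarking. Triangle
    surface meshes are represented as mathematical currents with a
    Gaussian reproducing kernel, a population template (anatomical mean
    shape) is estimated under the forward approach together with
    per-subject diffeomorphic-style deformations, and response-correlated
    shape modes and per-subject shape vectors are extracted by partial
    least squares regression with size residualization and Cook's-distance
    outlier screening. Includes mesh I/O (VTK legacy polydata, PLY, STL,
    OBJ), remeshing and passband smoothing, rigid ICP plus
    Procrustes-style alignment, centreline-based morphometry (length,
    tortuosity, curvature, diameters, arch height and width), geometric
    and k-fold template validation, and a seeded synthetic aortic-arch
    cohort generator with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
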