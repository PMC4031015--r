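Package: cellstrain
Title: Finite-Element Simulation of an Adherent Cell Under Cyclic Equibiaxial Substrate Strain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained structural finite-element simulator of a single
    adherent osteoblastic cell (viscoelastic cytoplasm, stiffer elastic
    nucleus, optional pre-tensioned actin stress-fiber network) bonded to an
    elastomeric membrane undergoing low-amplitude sinusoidal equibiaxial
    strain at 1-45 Hz. Provides parametric geometry generation, two-region
    quadratic tetrahedral meshing, a single-branch Generalized Maxwell
    (standard linear solid) constitutive update, tension-only pre-tensioned
    cable elements, implicit transient (Newmark) and quasi-static solvers,
    Von Mises stress / principal-strain post-processing with peak extraction
    and attachment-singularity exclusion, VTK-family field export, and a
    scenario suite comparing frequency sweeps, relaxation-time sweeps,
    iso-elastic nucleus and cytoskeletal variants against published
    reference values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
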