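Package: plaqhet
Title: Peak Cap Stress in Atherosclerotic Plaques with Heterogeneous Intima
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation study of the effect of intima stiffness heterogeneity
    on peak cap stress (PCS) in atherosclerotic plaque cross-sections.
    Generates synthetic histology-like plaque sections, subdivides the intima
    into stiffness clusters by k-means on greyscale intensity, samples cluster
    shear moduli by Latin hypercube sampling over the reported 1-149 kPa
    range, computes PCS with a plane-strain large-deformation nearly
    incompressible neo-Hookean finite-element solver (including initial
    stresses at the imaged 100 mmHg state), and attributes PCS variance to
    cluster stiffnesses with adaptive Legendre polynomial-chaos Sobol
    sensitivity indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    lhs,
    stats,
    tiff,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
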