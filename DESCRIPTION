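Package: sqmkit
Title: Semiempirical Model Hamiltonians with Slater-Koster Matrix
    Elements and Density-Fitted Coulomb Integrals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and fitting semiempirical quantum
    mechanics (SQM) model Hamiltonians for atomistic systems.  Two-center
    atomic-orbital matrix elements are assembled from radial
    Slater-Koster channels and real-spherical-harmonic rotation blocks;
    four-center Coulomb integrals are factored through an atom-local
    auxiliary basis with an exactly charge-conserving density fit that
    reduces to the NDDO approximation for orthogonal orbitals.  A
    brute-force s-Gaussian integral engine supplies reference integrals
    and sector-resolved full-configuration-interaction (FCI) spectra for
    hydrogen clusters, against which a minimal-basis seven-parameter
    hydrogen model is fit by per-distance least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
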