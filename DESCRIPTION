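Package: crystalce
Title: CE-HF and CE-B3LYP Model Interaction Energies for Molecular Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise intermolecular interaction energies for molecular
    crystals from a four-term model: scaled classical electrostatic,
    polarization, Grimme D2 dispersion and antisymmetrized-product
    exchange-repulsion energies computed from unperturbed monomer
    wavefunctions (HF/3-21G or B3LYP/6-31G(d,p)).  Includes a CIF reader
    with symmetry expansion and molecule perception, X-H bond-length
    normalization, neighbour-cluster and symmetry-unique pair generation,
    a compact Gaussian-basis SCF engine, energy-framework graph
    construction, converged pairwise lattice-energy summation, and
    least-squares calibration of the model scale factors against
    counterpoise-corrected benchmark energies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    yaml,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
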