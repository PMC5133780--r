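Package: lrfbo
Title: Linear Response Functions of Mayer Bond Orders and Electron Density
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Conceptual-DFT reactivity descriptors built on the uncoupled
    orbital linear response of a closed-shell single-determinant
    wavefunction.  Computes how every Mayer bond order (and the
    atom-condensed electron density) responds to a virtual local potential
    applied inside the Wigner-Seitz cell of any atom, with sigma/pi
    decomposition for planar systems and a Hammett-regression analysis
    layer.  Includes a self-contained restricted Hartree-Fock / B3LYP
    engine over contracted Gaussian basis sets (McMurchie-Davidson
    integrals), Euler-Maclaurin x Lebedev molecular quadrature, Molden
    file input/output, and analytic model wavefunctions for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
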