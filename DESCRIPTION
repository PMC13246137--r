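Package: neoscf
Title: Multicomponent Nuclear-Electronic Orbital Hartree-Fock with
    Simultaneous SCF Solvers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-consistent field engine for nuclear-electronic orbital
    Hartree-Fock (NEO-HF), in which electrons and designated protons are both
    treated quantum mechanically in Gaussian basis sets. Supports the nuclear
    Slater-determinant representation and the nuclear Hartree-product
    representation (with and without nuclear self-Coulomb/self-exchange terms),
    and optimizes electronic and nuclear orbitals simultaneously with coupled
    DIIS, quasi-Newton geometric direct minimization, or a trust-radius
    augmented-Hessian Davidson solver. Includes a McMurchie-Davidson Gaussian
    integral engine (overlap, mass-scaled kinetic, point-charge Coulomb, and
    two-cloud repulsion up to d functions), core and superposition-of-atomic-
    densities initial guesses for both particle types, built-in molecular
    fixtures, and a sweep harness for convergence experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
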