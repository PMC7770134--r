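Package: uaaff
Title: Charge Parametrization and MM/PBSA Analysis for Noncanonical Amino Acids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving Amber-compatible partial-charge parameters for
    noncanonical (unnatural) amino acids and for end-point binding free energy
    analysis. Implements restrained electrostatic potential (RESP) charge
    fitting with net-charge, equivalence and frozen-atom constraints,
    Merz-Kollman style ESP grid construction, convex blending of alpha-helix
    and beta-strand conformer charge sets against a quantum-mechanical
    relative-energy benchmark, an Amber-functional-form gas-phase energy model
    with restrained minimization, and single-trajectory MM/PBSA binding free
    energies with a finite-difference linearized Poisson-Boltzmann solver,
    Shrake-Rupley solvent accessible surface areas and per-residue energy
    decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
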