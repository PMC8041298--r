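Package: torsionfit
Title: Exact Least-Squares Fitting of Molecular Torsional Potentials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simultaneous fitting of Fourier torsional coefficients for all
    dihedral types of a molecule to reference dihedral-scan energies by the
    exact (algebraic) least-squares solution of the normal equations with
    parameter sharing across dihedral instances of the same type. Includes a
    box-constrained variant for bounded coefficients, a Metropolis Monte
    Carlo baseline for comparison, conversion between the Fourier cosine
    basis and the Ryckaert-Bellemans polynomial, RMSD-based evaluation of
    reconstructed energy profiles, a synthetic dihedral-scan generator with
    known ground truth, and GROMACS topology fragment export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
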