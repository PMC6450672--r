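Package: coacervate
Title: Thermodynamic Phase-Diagram Analysis of Protein-RNA Complex Coacervation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing liquid-liquid phase separation of charged
    protein-RNA mixtures that demix by complex coacervation, built around the
    tau-polyU system. Two complementary thermodynamic tracks are provided: a
    Flory-Huggins lattice model with a Voorn-Overbeek Debye-Huckel
    electrostatic term, including binodal construction by common tangent,
    per-condition chi fitting from cloud points and chi(T) = A + B/T
    regression; and a sequence-resolved coarse-grained polyelectrolyte field
    theory sampled by complex-Langevin dynamics on a periodic collocation
    mesh, with chemical-potential and osmotic-pressure operators and
    phase-coexistence determination from branch intersection. Supporting
    modules parse charged sequences, extract cloud points from turbidity
    sigmoids, map temperature to Bjerrum length and excluded volume, and
    generate synthetic turbidity curves and cloud-point grids for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
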