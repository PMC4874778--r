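Package: fgnupfield
Title: Mean-Field Thermodynamics of FG-Nucleoporin Assemblies and
    Transport Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Equilibrium mean-field theory for assemblies of intrinsically
    disordered FG nucleoporins (FG nups) interacting with nuclear transport
    proteins.  Implements the ternary lattice-fluid mixing free energy for
    polymer/protein/solvent mixtures with analytic chemical potentials and
    osmotic pressure; equilibrium conformations of surface-grafted FG nup
    layers in contact with a dilute protein reservoir (layer height, protein
    uptake, collapse/swelling response and scaling exponents); binary and
    ternary bulk phase coexistence (binodal, spinodal, critical point,
    tie-lines and transport-protein partitioning into the dense phase); and
    coil-globule dimensions of isolated chains.  Includes unit conversions
    between model volume fractions and molar concentrations, a library of
    named parameter scenarios, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
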