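Package: molkit
Title: Building Blocks for Molecular Modelling and Structural Bioinformatics
Version: 0.1.0
Authors@R: person("molkit", "developers", role = c("aut", "cre"),
    email = "molkit@example.org")
Description: A self-contained toolkit of composable building blocks for
    structural bioinformatics: a hierarchical molecular data model
    (system, chain, residue, atom) with a processor and selection
    mechanism; readers and writers for PDB, XYZ and MOL/SDF V2000;
    fragment-database driven structure preparation (atom-name
    normalization, hydrogen inference, bond building, residue
    validation, rotamer application); an AMBER-functional-form
    molecular mechanics force field with analytic gradients; energy
    minimizers (steepest descent, conjugate gradient, L-BFGS),
    velocity-Verlet molecular dynamics and a randomized quick
    optimizer; peptide construction from backbone torsions, a SMILES
    subset reader, heuristic bond-order assignment, kekulization and
    aromaticity perception; hydrogen-bond detection and a three-state
    secondary-structure assignment; and a command-line front end that
    chains the pieces into preparation pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
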