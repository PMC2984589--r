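# molkit

Composable building blocks for structural bioinformatics and molecular
modelling in R. The package provides, as a single self-contained toolkit,
the pieces that molecular-modelling pipelines keep re-implementing:

* a **hierarchical molecular data model** — system → chain → residue →
  atom plus a bond graph — with a processor mechanism (deterministic
  depth-first visits that may mutate the hierarchy) and expression-based
  atom **selections** (`element(H)`, `backbone AND residueID(5-10)`, …);
* **file I/O** for PDB (coordinate section, ATOM/HETATM/TER/CONECT),
  XYZ and MOL/SDF V2000, round-trip stable at each format's precision;
* a **fragment database** of residue templates (ideal internal
  coordinates, force-field types, partial charges, intra-residue bonds
  for the 20 standard amino acids in all terminal variants, plus water)
  driving structure preparation: atom-name normalization, hydrogen
  inference, bond building, residue validation, and rotamer application;
* an **AMBER-functional-form force field** with analytic gradients,

  E = Σ k_r (r−r₀)² + Σ k_θ (θ−θ₀)² + Σ (V_n/2)(1+cos(nφ−γ))
    + Σ ε[(r_min/r)¹² − 2(r_min/r)⁶] + Σ 332.0637 q_i q_j / r,

  with standard 1-2/1-3 exclusions, scaled 1-4 pairs (scee = 1.2,
  scnb = 2.0) and a hard distance cutoff;
* **minimizers** (steepest descent, Polak–Ribière+ conjugate gradient,
  L-BFGS) and **velocity-Verlet dynamics** with a Berendsen thermostat,
  all selection-aware: the full system contributes to the energy while
  only *movable* (selected) atoms are displaced, plus a randomized
  quick optimizer (heated MD bursts alternating with minimization,
  keeping the best conformation);
* **molecule construction**: peptides from sequence + φ/ψ/ω torsions via
  sequential internal-coordinate (NeRF) placement, and a SMILES-subset
  reader with implicit-hydrogen filling;
* **cheminformatics**: penalty-scored bond-order assignment
  (branch-and-bound, results sorted by penalty), kekulization (perfect
  matching on the aromatic subgraph) and Hückel aromaticity perception
  over the smallest set of smallest rings;
* **analysis**: geometric hydrogen-bond detection, an electrostatic
  backbone H-bond energy model with a three-state (H/E/C) secondary
  structure assignment, and Kabsch superposition RMSD.

Units everywhere: Ångström, degrees, kcal/mol, elementary charges, amu,
femtoseconds. Torsions follow the IUPAC sign convention.

## Worked example

Build an α-helical peptide, strip and re-infer its hydrogens, validate
it, and relax the hydrogen positions with the heavy atoms frozen:

```r
library(molkit)

helix <- build_peptide("AEKLFSR", phi = -57, psi = -47)
helix
#> <molsys: 1 chain(s), 7 residue(s), 124 atom(s), 124 bond(s)>
assign_secondary_structure(helix)
#> [1] "C" "H" "H" "H" "H" "H" "C"

strip_hydrogens(helix)
normalize_names(helix)
add_hydrogens(helix)          # rebuilt from fragment templates
build_bonds(helix)
is_clean(check_residues(helix))
#> [1] TRUE

deselect(helix)
ff <- ff_setup(helix)         # types + charges + interaction lists
compute_energy(ff)
#> E_total = 412.114029 kcal/mol  (stretch 0.0570, bend 1.9765,
#>   torsion 0.1275, vdw 558.2624, elec -148.3093)

apply_selection(helix, "element(H)")   # 64 hydrogens become movable
ff$movable <- set_movable_from_selection(helix)
minimize_lbfgs(helix, ff, minimizer_options(max_iterations = 200,
                                            grad_tolerance = 0.5))
#> minimizer: E = -125.133607 kcal/mol after 14 iterations
#>   (converged, RMS grad 0.3829)
write_pdb(helix, "helix.pdb")
```

The initial energy is dominated by van-der-Waals contacts of the
freshly placed template hydrogens; relaxing only the hydrogens removes
them (−125 kcal/mol) while every heavy atom stays bit-identical.

## Command line

The same pipeline is scriptable through `molkit_main()` (or the
`inst/exec/molkit` launcher):

```sh
molkit build-peptide AAAAAAAAAAAA --phi -57 --psi -47 --out helix.pdb
molkit prepare input.pdb --out prepared.pdb --iterations 50 --output-frequency 1
molkit convert prepared.pdb out.xyz
molkit analyze helix.pdb --ss --hbonds --out report.txt
molkit assign-bonds ligand.sdf --max-results 5 --out assigned.sdf
molkit minimize input.pdb --method lbfgs --select "element(H)" --out min.pdb
molkit selftest
```

`prepare` runs: read PDB → normalize names → add hydrogens → build
bonds → check residues (report printed) → force-field setup → select
`element(H)` → conjugate-gradient minimization (50 iterations, energy
logged every iteration) → write PDB. Exit codes: 0 ok, 1 check/selftest
failure, 2 I/O error, 3 parameter error, 4 numerical failure.

## Bundled data

`inst/extdata/` ships plain-text, self-authored data files: residue
templates (`fragments.txt`; terminal variants are derived at load
time), force-field parameters (`ff_params.txt`), atom-name aliases, an
illustrative rotamer library, and the bond-order valence-penalty
table. `tools/make_data.R` regenerates all of them and documents every
geometric and charge convention used.
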