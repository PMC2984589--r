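---
title: "molkit: models, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{molkit: models, algorithms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the scientific and numerical decisions behind
molkit: what each component computes, which conventions it fixes, what
the bundled data do and do not represent, and where the known limits
are. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data model and its contracts

A molecular system is a rooted hierarchy (system → chain → residue →
atom) over a columnar store with reference semantics, plus a global
bond table. Two contracts matter downstream:

* **Document order.** Traversal, I/O and every "deterministic order"
  promise follow insertion order, never serial numbers. Serial numbers
  are I/O metadata only. This choice makes behavior reproducible under
  renumbering; it is our convention, fixed here rather than inherited
  from any particular prior toolkit.
* **Reference identity.** Atoms are identified by row within their
  system; deep copies (`sys_copy`) are fully independent.

Processors visit the hierarchy depth-first (system, then each chain,
its residues, their atoms) and may mutate it; an atom visit may return
`"delete"`, applied after traversal so the visit sequence stays
well-defined. Selections are pure predicate trees; flags are written
only by `apply_selection`.

**Torsion sign convention.** `measure_dihedral` implements the IUPAC
convention: cis = 0°, sign by the right-hand rule about the b→c axis,
range (−180°, 180°]. We cross-checked the sign against three
independent implementations (biotite, MDAnalysis, and the standard
two-vector `atan2` reference formula); all agree with the values
produced here, e.g. the probe configuration (1,0,0), (0,0,0), (0,1,0),
(0,1,1) measures −90°. `place_atom` (NeRF placement) uses the same
convention, so placement and measurement round-trip to ~1e−7°.

## Fragment database and structure preparation

`inst/extdata/fragments.txt` holds one template per standard amino
acid (plus water): atom names, elements, force-field types, partial
charges, a Z-matrix (bond length, angle, torsion relative to three
earlier atoms; `-X` references reach into the preceding residue), and
the intra-residue bond list. Only the *internal* variant is stored;
the loader derives `n_terminal` (protonated amine: N3 type, H1–H3,
prolines H1–H2), `c_terminal` (carboxylate: O/OXT as O2) and `free`
variants mechanically, then re-validates them. Explicit variant
sections in a user-supplied file override the derivation.

The geometry is idealized: standard bond lengths and angles, planar
regular rings (the tryptophan benzo ring closes within ~2% of its
nominal bond length, inside the 15% validation tolerance), side-chain
torsions at anti (180°) defaults, and L-chirality throughout (verified
against the CCD ideal alanine by signed volume at CA). The proline
ring's internal coordinates were measured from a real peptide
structure, because the free amino acid's pyramidal amine nitrogen is
the wrong reference for a planar peptide amide.

Charges are a self-authored, AMBER-style set: the backbone six
(N −0.4157, H 0.2719, CA 0.0337, HA 0.0823, C 0.5973, O −0.5679) use
familiar published magnitudes; side chains start from coarse per-type
seeds and the residual needed to reach the residue's integer formal
charge is spread evenly over side-chain carbons. Every variant
therefore sums to an exact integer at the file's 6-decimal precision —
a validated invariant, not an aspiration. Histidine is modeled as the
neutral ND1-H tautomer only.

Preparation operations are all idempotent by construction:
`normalize_names` (padding strip, digit-first hydrogen rewrite,
alias table), `add_hydrogens` (place template hydrogens from internal
coordinates; synthesize a deterministic frame when a torsion reference
is missing, which is how isolated water gets its 0.96 Å / 104.52°
geometry), and `build_bonds` (template pairs, peptide C–N within
2.0 Å of sequence-adjacent residues, disulfide SG–SG within 2.5 Å —
cutoffs are our stated defaults, configurable). `check_residues`
compares against the template's reference geometry and reports
missing/unknown atoms, >15% bond-length deviations, >0.05 e charge
anomalies, and non-bonded contacts under 0.5 Å.

The bundled rotamer library is deliberately illustrative: three χ1
wells (180°, −60°, +60°) with probabilities 0.5/0.3/0.2 and χ2+ at
anti, format-compatible with richer libraries. It demonstrates the
machinery (probability-sorted lookup, χ application through rigid
rotation); it is not a statistical library.

## Force field

The functional form is the AMBER one: harmonic stretches and bends,
cosine torsion series, 12-6 Lennard-Jones (ε, r_min combining as
ε_ij = √(ε_i ε_j), r_ij = r_i + r_j) and Coulomb with
332.0637 kcal·Å/(mol·e²). Exclusions are standard: 1-2 and 1-3 pairs
excluded, 1-4 pairs divided by scnb = 2.0 (vdW) and scee = 1.2
(electrostatics). Nonbonded truncation is a hard cutoff (default 12 Å,
0 disables); no switching function, no periodicity, ε = 1.

Choices worth flagging:

* **Parameters are derived from the templates.** `tools/make_data.R`
  enumerates every typed bond/angle tuple occurring in built test
  peptides (all residues, all variants, including junctions) and emits
  r₀/θ₀ as the mean observed template geometry with force constants
  from element-class rules. Torsions are wildcard entries per middle
  bond-type pair. Coverage is checked at generation time, so a missing
  parameter is impossible for template-derived systems and an error
  (naming the tuple) otherwise.
* **No improper torsions.** sp² planarity is maintained by the n = 2,
  γ = 180° proper-torsion wildcards; for the gentle minimizations this
  package targets (hydrogen placement, strain relief) that is
  sufficient, and it keeps the term list to the stated five.
* **Movable vs energetic atoms.** The full system always contributes
  to the energy; the selection only gates displacement. Whether frozen
  atoms should also leave the energy is genuinely ambiguous in the
  tradition this follows; we fix the "full energy, masked motion"
  reading and test it (frozen atoms are bit-identical after any
  optimizer or MD run).
* Analytic gradients are validated against central finite differences
  (h = 1e−5 Å) to <1e−6 relative error on randomized clash-free
  conformations. Clash-free matters: inside an r⁻¹² wall the
  finite-difference *oracle* itself loses accuracy (truncation error
  grows with the third derivative), so the sampled world rejects
  conformations with non-bonded contacts under 1.2 Å rather than
  asserting against a broken oracle.

## Minimization and dynamics

All three minimizers share one loop: RMS-gradient stopping rule
(default 0.1 kcal/mol/Å), backtracking Armijo line search (c₁ = 1e−4,
halving, first trial displacement 1 Å along the unit direction, 30
backtracks), energy trace recorded per accepted step and therefore
non-increasing by construction. Armijo-only (rather than strong Wolfe)
is a documented simplification; the Polak–Ribière+ restart (β⁺ = max(0, β),
restart on non-descent or every 3N steps) and the L-BFGS curvature
guard (skip pairs with sᵀy ≤ 1e−10, reset memory when the two-loop
direction fails descent) compensate in practice.

The `line_search = "exact"` variant solves φ′(α) = 0 by derivative
root-finding when a gradient is available. This exists for the theory
contracts: on an n-dimensional quadratic, conjugate gradient with
exact line search terminates in ≤ n iterations, which the acceptance
suite checks for n = 2…5 — a property that golden-section line
searches are not accurate enough to preserve on ill-conditioned
problems.

Dynamics integrate velocity-Verlet in Å/fs/amu/kcal·mol⁻¹ units
(1 kcal·mol⁻¹·Å⁻¹/amu = 4.184 × 10⁻⁴ Å/fs²), Maxwell–Boltzmann initial
velocities from a single integer seed drawn through a private RNG
stream (the caller's RNG state is untouched), optional Berendsen
rescaling. Energy-conservation tests use a small-amplitude
(0.01 Å-stretched) carbon-like harmonic diatomic: drift stays under
1e−4 kcal/mol over 1000 × 0.5 fs steps and shrinks ~4× when the
timestep halves, the symplectic O(Δt²) signature. The quick optimizer
alternates seeded 300 K / 100-step / 1 fs bursts with CG minimization
and keeps the lowest-energy conformation — the schedule is our
instantiation of the idea, and the keep-best rule guarantees its
result is never worse than plain minimization.

## Builders and bond-order perception

`build_peptide` extends the chain by sequential NeRF placement in
template order; φ, ψ, ω enter as the torsions of C(i), N(i+1) and
CA(i) respectively, so the measured interior torsions reproduce the
request to ~1e−3° (an acceptance criterion). The first residue seeds
the frame (N at origin, CA on +x, C in a deterministic synthetic
plane). φ of the first and ψ of the last residue are geometrically
undefined and ignored.

The SMILES reader covers the declared subset (organic-subset atoms,
brackets with charge/H-count, −/=/#, branches, ring closures including
`%nn`, lowercase aromatics) and rejects stereo marks and isotopes
explicitly. Aromatic input is kekulized by a backtracking perfect
matching over the aromatic subgraph in which pyrrole-type N/O/S
(lone-pair donors) are excluded from receiving double bonds; implicit
hydrogens then fill to charge-adjusted default valences (N⁺ 4, O⁻ 1,
…). SMILES-derived molecules are graphs; their coordinates are
placeholders, never geometry.

Bond-order assignment scores a complete assignment as the sum of
atomic penalties, 32 per unit of deviation from the nearest allowed
valence (C 4; N 3, N⁺ 4; O 2, O⁻ 1; S 2/4/6; P 3/5; H 1; halogens 1 —
a data file, so richer tables drop in). The branch-and-bound
enumerates {1,2,3} per heavy-heavy bond, scoring atoms as soon as
their last bond is fixed, and returns assignments sorted by penalty
with a deterministic lexicographic tie-break. "Sorted by probability"
in the tradition this mirrors becomes "ascending penalty" here — a
stated proxy, and the first result is proved globally minimal against
exhaustive enumeration on every test molecule (≤ 8 bonds).
Aromaticity perception computes SSSR (per-edge shortest cycles reduced
to a GF(2)-independent basis) and applies Hückel 4n+2 counting
(in-ring double bond: 1 π electron; pyrrole-type heteroatom: 2;
carbocation: 0); exocyclic doubles disqualify a ring here, which is
conservative for quinone-like systems.

## Analysis

Hydrogen-bond detection is geometric (donor N/O/S with H, acceptor
N/O, D···A ≤ 3.5 Å, D–H···A ≥ 120°; configurable). The backbone model
is the electrostatic four-distance form
E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) with the −0.5
kcal/mol threshold and a −9.9 clash sentinel below 0.5 Å. Secondary
structure is a reduced three-state scheme over that H-bond set: two
consecutive 4-turns make residues i+1…i+4 helical; parallel or
antiparallel bridge patterns mark strands; helix wins conflicts;
everything else (including residues missing backbone atoms) is coil.
The full eight-state scheme (3₁₀/π helices, turns, bends, isolated
bridges) is deliberately out of scope. A builder-generated
(−57°, −47°) helix labels all interior residues H and a fully extended
chain labels all C — both are acceptance criteria, and both are
statements about idealized template geometry, not about prediction
quality on experimental structures.

## What the synthetic world does and does not establish

Every test input is generated in code: template-built peptides,
fragment-derived waters, random free molecules (random trees with
random orders and coordinates) for I/O round trips, random predicate
trees for selection equivalence. This world exercises contracts —
determinism, idempotence, analytic identities, oracle equivalence,
conservation laws — on clean, idealized structures. It does not
contain disorder, alternate locations beyond synthetic cases, missing
densities, unusual residues, or experimental noise; a green suite
therefore establishes correctness of the algorithms on their stated
domain, not robustness across the PDB archive. The PDB parser's
policies for that messier world (altLoc highest-occupancy keep,
hetero-atoms always read, insertion codes part of residue identity,
lax-by-default parsing with per-line errors in strict mode) are stated
defaults of this package, chosen to match common practice.

## Known limitations

* Parameters and charges are a minimal self-authored set for the 20
  amino acids + water: adequate for preparation-grade minimization,
  not for quantitative energetics; ligands need `assign_bond_orders`
  but have no bundled force-field types.
* No improper torsions, no switching function, no PME/periodicity, no
  implicit solvent, no SHAKE.
* Proline ring geometry is a single fixed pucker; ring flexibility is
  not modeled, and the template amide improper is exactly planar only
  near φ ≈ −57°.
* The rotamer library is illustrative; χ sampling is the user's job.
* SMILES writing, stereochemistry, tautomers and SMARTS matching are
  out of scope.
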