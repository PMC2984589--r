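# Peptide building, SMILES parsing, valence filling, bond-order
# assignment, kekulization, aromaticity.

test_that("build_peptide recovers every specified torsion", {
  s <- build_peptide("AAA", phi = -57, psi = -47, db = frag_db)
  expect_equal(n_residues(s), 3)
  xyz <- coords(s)
  at <- function(ri, nm) xyz[find_atom(s, ri, nm), ]
  for (i in 2:3)
    expect_equal(measure_dihedral(at(i - 1, "C"), at(i, "N"), at(i, "CA"),
                                  at(i, "C")), -57, tolerance = 1e-3)
  for (i in 1:2)
    expect_equal(measure_dihedral(at(i, "N"), at(i, "CA"), at(i, "C"),
                                  at(i + 1, "N")), -47, tolerance = 1e-3)
  for (i in 1:2)
    expect_equal(abs(measure_dihedral(at(i, "CA"), at(i, "C"), at(i + 1, "N"),
                                      at(i + 1, "CA"))), 180,
                 tolerance = 1e-3)

  ## per-residue vectors work too
  v <- build_peptide("AAAA", phi = c(-57, -60, -120, -70),
                     psi = c(-47, -45, 130, 150), db = frag_db)
  xyz <- coords(v)
  at <- function(ri, nm) xyz[find_atom(v, ri, nm), ]
  expect_equal(measure_dihedral(at(2, "C"), at(3, "N"), at(3, "CA"),
                                at(3, "C")), -120, tolerance = 1e-3)
  expect_equal(measure_dihedral(at(3, "N"), at(3, "CA"), at(3, "C"),
                                at(4, "N")), 130, tolerance = 1e-3)
})

test_that("single-residue build equals the free-variant template", {
  g <- build_peptide("G", db = frag_db)
  tpl <- frag_db$templates[["GLY.free"]]
  expect_identical(g$atoms$name, tpl$atoms$name)
  expect_identical(g$atoms$element, tpl$atoms$element)
  expect_equal(n_bonds(g), nrow(tpl$bonds))

  ## extended dipeptide CA-CA distance ~ 3.80 A
  e <- build_peptide("AA", phi = -180, psi = 180, db = frag_db)
  d <- measure_distance(coords(e)[find_atom(e, 1, "CA"), ],
                        coords(e)[find_atom(e, 2, "CA"), ])
  expect_equal(d, 3.80, tolerance = 0.05 / 3.80)

  expect_error(build_peptide("AXB", db = frag_db), "position 2")
})

test_that("every residue letter builds clean in every variant", {
  for (a in names(molkit:::AA3)) {
    s <- build_peptide(paste0("G", a, "G"), db = frag_db)
    expect_true(is_clean(check_residues(s, frag_db)), info = a)
    expect_equal(total_charge(s),
                 frag_db$templates[[paste0(molkit:::AA3[[a]],
                                           ".internal")]]$net_charge,
                 tolerance = 1e-6, info = a)
  }
})

test_that("parse_smiles covers the declared grammar", {
  s <- parse_smiles("CCO")
  expect_equal(sum(s$atoms$element != "H"), 3)
  expect_equal(n_atoms(s), 9)  # ethanol with implicit H
  heavy_bonds <- s$bonds[s$atoms$element[s$bonds$i] != "H" &
                         s$atoms$element[s$bonds$j] != "H", ]
  expect_equal(nrow(heavy_bonds), 2)
  expect_true(all(heavy_bonds$order == 1))

  ring <- parse_smiles("C1CCCCC1")
  expect_equal(sum(ring$atoms$element == "C"), 6)
  cc <- ring$bonds[ring$atoms$element[ring$bonds$i] == "C" &
                   ring$atoms$element[ring$bonds$j] == "C", ]
  expect_equal(nrow(cc), 6)
  expect_true(all(cc$order == 1))

  ## bracket atoms: charge and explicit H count
  amm <- parse_smiles("[NH4+]")
  expect_equal(sum(amm$atoms$element == "N"), 1)
  expect_equal(sum(amm$atoms$element == "H"), 4)
  expect_equal(amm$atoms$formal_charge[1], 1L)

  co2 <- parse_smiles("O=C=O")
  expect_equal(sum(co2$atoms$element == "H"), 0)
  expect_true(all(co2$bonds$order == 2))

  ## triple bonds, branches, %nn closures
  hcn <- parse_smiles("C#N")
  expect_equal(max(hcn$bonds$order), 3)
  expect_equal(sum(hcn$atoms$element == "H"), 1)
  iso <- parse_smiles("CC(C)C")
  expect_equal(sum(iso$atoms$element == "C"), 4)
  big <- parse_smiles("C%12CCCCC%12")
  expect_equal(sum(big$atoms$element == "C"), 6)

  ## declared errors
  expect_error(parse_smiles("C1CC"), "ring closure")
  expect_error(parse_smiles("C(C"), "parenthesis")
  expect_error(parse_smiles("C/C=C/C"), "stereo")
  expect_error(parse_smiles("[13C]"), "bracket")
})

test_that("benzene kekulizes to 3 alternating double bonds", {
  b <- parse_smiles("c1ccccc1")
  ring_bonds <- b$bonds[b$atoms$element[b$bonds$i] == "C" &
                        b$atoms$element[b$bonds$j] == "C", ]
  expect_equal(sort(ring_bonds$order), c(1, 1, 1, 2, 2, 2))
  ## no carbon carries two double bonds
  for (a in which(b$atoms$element == "C"))
    expect_lte(sum(b$bonds$order[atom_bonds(b, a)] == 2), 1)

  ## pyrrole: nitrogen keeps single bonds
  p <- parse_smiles("c1cc[nH]c1")
  expect_equal(sum(p$bonds$order == 2), 2)
  nb <- atom_bonds(p, which(p$atoms$element == "N")[1])
  expect_true(all(p$bonds$order[nb] == 1))
  ## pyrrole N carries exactly one H
  nn <- which(p$atoms$element == "N")
  expect_equal(sum(p$atoms$element[atom_neighbors(p, nn)] == "H"), 1)

  ## no aromatic bonds -> kekulize is the identity
  e <- parse_smiles("CCO")
  pre <- e$bonds
  kekulize(e)
  expect_identical(e$bonds, pre)
})

test_that("assign_bond_orders equals exhaustive search on small inputs", {
  cases <- c("CCO", "C=O", "CC(=O)O", "c1ccccc1", "C#N", "CS(=O)C")
  for (smi in cases) {
    s <- parse_smiles(smi)
    s2 <- sys_copy(s)
    s2$bonds$order <- 1  # forget the orders
    got <- assign_bond_orders(s2, max_results = 3)
    want <- exhaustive_bond_orders(s2)
    expect_equal(got[[1]]$penalty, want$penalty, info = smi)
    ## penalties are non-decreasing
    pens <- vapply(got, `[[`, numeric(1), "penalty")
    expect_true(all(diff(pens) >= 0), info = smi)
  }

  ## ethane connectivity: unique zero-penalty assignment, all single
  e <- parse_smiles("CC")
  e$bonds$order <- 1
  got <- assign_bond_orders(e, max_results = 10)
  expect_equal(got[[1]]$penalty, 0)
  expect_true(all(got[[1]]$orders == 1))
  expect_true(length(got) == 1 || got[[2]]$penalty > 0)

  ## benzene connectivity: exactly the 2 Kekule structures first
  b <- parse_smiles("c1ccccc1")
  b$bonds$order <- 1
  got <- assign_bond_orders(b, max_results = 5)
  expect_equal(got[[1]]$penalty, 0)
  expect_equal(got[[2]]$penalty, 0)
  expect_gt(got[[3]]$penalty, 0)
  free <- which(b$atoms$element[b$bonds$i] != "H" &
                b$atoms$element[b$bonds$j] != "H")
  o1 <- got[[1]]$orders[free]; o2 <- got[[2]]$orders[free]
  expect_equal(sort(o1), c(1, 1, 1, 2, 2, 2))
  expect_equal(sort(o2), c(1, 1, 1, 2, 2, 2))
  expect_false(identical(o1, o2))
})

test_that("fill_valence honours charge-adjusted default valences", {
  m <- parse_smiles("C")           # methane
  expect_equal(sum(m$atoms$element == "H"), 4)
  w <- parse_smiles("[OH-]")
  expect_equal(sum(w$atoms$element == "H"), 1)
  n <- parse_smiles("N")
  expect_equal(sum(n$atoms$element == "H"), 3)
})

test_that("perceive_aromaticity applies the Hueckel rule on SSSR", {
  b <- parse_smiles("c1ccccc1")    # kekulized on parse
  perceive_aromaticity(b)
  cc <- b$bonds[b$atoms$element[b$bonds$i] == "C" &
                b$atoms$element[b$bonds$j] == "C", ]
  expect_true(all(cc$order == BOND_AROMATIC))

  ch <- parse_smiles("C1CCCCC1")   # cyclohexane: no pi electrons
  perceive_aromaticity(ch)
  expect_false(any(ch$bonds$order == BOND_AROMATIC))

  ## cyclobutadiene pattern: 4 pi electrons fails 4n+2
  cb <- parse_smiles("C1=CC=C1")
  perceive_aromaticity(cb)
  expect_false(any(cb$bonds$order == BOND_AROMATIC))

  ## pyrrole: N lone pair completes the sextet
  p <- parse_smiles("c1cc[nH]c1")
  perceive_aromaticity(p)
  ring_atoms <- which(p$atoms$element %in% c("C", "N"))
  ring_bonds <- p$bonds[p$bonds$i %in% ring_atoms &
                        p$bonds$j %in% ring_atoms, ]
  expect_true(all(ring_bonds$order == BOND_AROMATIC))

  ## stability: perceive -> kekulize -> perceive is idempotent
  b2 <- parse_smiles("c1ccccc1")
  perceive_aromaticity(b2)
  kekulize(b2)
  perceive_aromaticity(b2)
  snap <- b2$bonds$order
  kekulize(b2)
  perceive_aromaticity(b2)
  expect_identical(b2$bonds$order, snap)
})

test_that("find_sssr returns an independent basis of smallest rings", {
  b <- parse_smiles("c1ccccc1")
  rings <- find_sssr(b)
  expect_length(rings, 1)
  expect_length(rings[[1]], 6)

  ## naphthalene-like fusion: 2 six-rings, not the 10-ring
  n <- parse_smiles("C1CCC2CCCCC2C1")
  rings <- find_sssr(n)
  expect_length(rings, 2)
  expect_true(all(lengths(rings) == 6))

  expect_length(find_sssr(parse_smiles("CCO")), 0)
})
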