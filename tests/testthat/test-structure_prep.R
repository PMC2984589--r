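# Fragment-database preparation: normalization, hydrogen inference,
# bond building, residue checking, rotamers.

test_that("normalize_names strips padding, rewrites aliases, idempotent", {
  s <- new_system()
  r <- add_residue(s, add_chain(s, "A"), "ALA", 1)
  add_atom(s, r, " CA ", "C", c(0, 0, 0))
  add_atom(s, r, "1HB", "H", c(1, 0, 0))
  add_atom(s, r, "HN", "H", c(2, 0, 0))
  add_atom(s, r, "OT1", "O", c(3, 0, 0))
  add_atom(s, r, "OT2", "O", c(4, 0, 0))
  add_atom(s, r, "QQ", "C", c(5, 0, 0))  # unknown stays intact
  normalize_names(s, frag_db)
  expect_identical(s$atoms$name, c("CA", "HB1", "H", "O", "OXT", "QQ"))
  snap <- s$atoms$name
  normalize_names(s, frag_db)
  expect_identical(s$atoms$name, snap)
})

test_that("add_hydrogens places template hydrogens at ideal geometry", {
  ## water: O-H 0.96, H-O-H 104.52
  w <- make_water()
  expect_equal(n_atoms(w), 3)
  xyz <- coords(w)
  expect_equal(measure_distance(xyz[1, ], xyz[2, ]), 0.96, tolerance = 1e-9)
  expect_equal(measure_distance(xyz[1, ], xyz[3, ]), 0.96, tolerance = 1e-9)
  expect_equal(measure_angle(xyz[2, ], xyz[1, ], xyz[3, ]), 104.52,
               tolerance = 1e-3)

  ## internal ALA with all heavy atoms gains exactly H, HA, HB1..3
  s <- build_peptide("GAG", db = frag_db)
  strip_hydrogens(s)
  heavy_before <- coords(s)
  n_before <- n_atoms(s)
  add_hydrogens(s, frag_db)
  added <- sort(s$atoms$name[s$atoms$res == 2 & s$atoms$element == "H"])
  expect_identical(added, sort(c("H", "HA", "HB1", "HB2", "HB3")))
  ## heavy atoms never move
  expect_identical(coords(s)[seq_len(n_before), ], heavy_before)

  ## idempotence: complete system gains nothing
  n_now <- n_atoms(s)
  add_hydrogens(s, frag_db)
  expect_equal(n_atoms(s), n_now)
})

test_that("build_bonds creates template, peptide and disulfide bonds", {
  s <- build_peptide("AA", db = frag_db)
  ## peptide bond present exactly once
  ci <- find_atom(s, 1, "C"); nj <- find_atom(s, 2, "N")
  hit <- which(s$bonds$i == min(ci, nj) & s$bonds$j == max(ci, nj))
  expect_length(hit, 1)
  ## total bond count = sum of template intra bonds + 1 peptide bond
  tpl1 <- frag_db$templates[["ALA.n_terminal"]]
  tpl2 <- frag_db$templates[["ALA.c_terminal"]]
  expect_equal(n_bonds(s), nrow(tpl1$bonds) + nrow(tpl2$bonds) + 1)

  ## idempotence
  nb <- n_bonds(s)
  build_bonds(s, frag_db)
  expect_equal(n_bonds(s), nb)

  ## distant residues are not joined
  far <- build_peptide("AA", db = frag_db)
  xyz <- coords(far)
  xyz[far$atoms$res == 2, ] <- xyz[far$atoms$res == 2, ] + 500
  set_coords(far, xyz)
  far$bonds <- far$bonds[0, ]
  build_bonds(far, frag_db)
  ci <- find_atom(far, 1, "C"); nj <- find_atom(far, 2, "N")
  expect_false(any(far$bonds$i == min(ci, nj) & far$bonds$j == max(ci, nj)))

  ## disulfide within 2.5 A
  cys2 <- build_peptide("CC", db = frag_db)
  sg <- which(cys2$atoms$name == "SG")
  xyz <- coords(cys2)
  xyz[sg[2], ] <- xyz[sg[1], ] + c(2.04, 0, 0)
  set_coords(cys2, xyz)
  build_bonds(cys2, frag_db)
  expect_true(any(cys2$bonds$i == min(sg) & cys2$bonds$j == max(sg)))
})

test_that("check_residues reports the spec's finding kinds", {
  ## clean built dipeptide -> empty report
  s <- build_peptide("AS", db = frag_db)
  rep <- check_residues(s, frag_db)
  expect_true(is_clean(rep))

  ## missing CB -> missing_atom error naming CB
  s2 <- build_peptide("GAG", db = frag_db)
  delete_atoms(s2, find_atom(s2, 2, "CB"))
  rep <- check_residues(s2, frag_db)
  miss <- rep[rep$kind == "missing_atom", ]
  expect_true(any(grepl("CB", miss$message)))
  expect_true(all(miss$severity == "error"))

  ## stretched peptide bond -> bond_length_deviation warning
  s3 <- build_peptide("AA", db = frag_db)
  xyz <- coords(s3)
  shift <- xyz[find_atom(s3, 2, "N"), ] - xyz[find_atom(s3, 1, "C"), ]
  shift <- shift / sqrt(sum(shift^2)) * (2.0 - 1.329)
  sel <- s3$atoms$res == 2
  xyz[sel, ] <- sweep(xyz[sel, , drop = FALSE], 2, -shift)
  set_coords(s3, xyz)
  rep <- check_residues(s3, frag_db)
  expect_true(any(rep$kind == "bond_length_deviation"))

  ## unknown residue -> error finding
  s4 <- new_system()
  r <- add_residue(s4, add_chain(s4, "A"), "XYZ", 1)
  add_atom(s4, r, "C1", "C", c(0, 0, 0))
  rep <- check_residues(s4, frag_db)
  expect_true(any(rep$kind == "unknown_residue" & rep$severity == "error"))

  ## clash detection: non-bonded pair closer than 0.5 A
  s5 <- build_peptide("AA", db = frag_db)
  xyz <- coords(s5)
  xyz[find_atom(s5, 2, "CB"), ] <- xyz[find_atom(s5, 1, "CB"), ] + 0.2
  set_coords(s5, xyz)
  rep <- check_residues(s5, frag_db)
  expect_true(any(rep$kind == "atom_clash" & rep$severity == "error"))

  ## stray atom -> unknown_atom warning
  s6 <- build_peptide("AA", db = frag_db)
  add_atom(s6, 1, "XX", "C", c(30, 30, 30))
  rep <- check_residues(s6, frag_db)
  expect_true(any(rep$kind == "unknown_atom" & rep$severity == "warning"))
})

test_that("prepare pipeline is idempotent on its own output", {
  s <- build_peptide("ASA", db = frag_db)
  strip_hydrogens(s)
  normalize_names(s, frag_db); add_hydrogens(s, frag_db)
  build_bonds(s, frag_db)
  xyz1 <- coords(s); nb1 <- n_bonds(s)
  normalize_names(s, frag_db); add_hydrogens(s, frag_db)
  build_bonds(s, frag_db)
  expect_identical(coords(s), xyz1)
  expect_equal(n_bonds(s), nb1)
  expect_true(is_clean(check_residues(s, frag_db)))
})

test_that("rotamer library loads, sorts and applies", {
  lib <- load_rotamer_library()
  for (df in lib) {
    expect_equal(sum(df$probability), 1, tolerance = 1e-6)
    expect_true(all(diff(df$probability) <= 0))
  }
  best <- most_likely_rotamer(lib, "SER")
  expect_equal(best$probability, max(lib$SER$probability))
  expect_equal(best$chi1, 180)
  expect_error(most_likely_rotamer(lib, "QQQ"), "no rotamers")

  ## chi1 = 60 round trip on SER
  s <- build_peptide("GSG", db = frag_db)
  apply_rotamer(s, 2, c(60))
  xyz <- coords(s)
  idx <- vapply(c("N", "CA", "CB", "OG"), function(nm) find_atom(s, 2, nm),
                integer(1))
  expect_equal(measure_dihedral(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ],
                                xyz[idx[4], ]), 60, tolerance = 1e-6)
  ## backbone untouched
  bb <- vapply(c("N", "CA", "C", "O"), function(nm) find_atom(s, 2, nm),
               integer(1))
  s0 <- build_peptide("GSG", db = frag_db)
  expect_equal(coords(s)[bb, ], coords(s0)[bb, ], tolerance = 1e-12)

  ## ALA has no chi: applying any rotamer is a no-op
  a <- build_peptide("GAG", db = frag_db)
  pre <- coords(a)
  apply_rotamer(a, 2, c(60))
  expect_identical(coords(a), pre)

  ## A then B then A returns to A exactly
  s1 <- build_peptide("GSG", db = frag_db)
  apply_rotamer(s1, 2, c(60)); xa <- coords(s1)
  apply_rotamer(s1, 2, c(-60)); apply_rotamer(s1, 2, c(60))
  expect_equal(coords(s1), xa, tolerance = 1e-6)

  ## missing chi atom errors with the torsion named
  s2 <- build_peptide("GSG", db = frag_db)
  delete_atoms(s2, find_atom(s2, 2, "OG"))
  expect_error(apply_rotamer(s2, 2, c(60)), "chi1")
})

test_that("fragment templates validate: integer charges, ordered refs", {
  for (key in names(frag_db$templates)) {
    tpl <- frag_db$templates[[key]]
    expect_equal(sum(tpl$atoms$charge), tpl$net_charge, tolerance = 1e-6,
                 info = key)
    expect_false(anyDuplicated(tpl$atoms$name) > 0, info = key)
  }
  ## lookup total for the bundled set: 20 residues x 4 variants + water
  expect_length(frag_db$templates, 81)
})
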