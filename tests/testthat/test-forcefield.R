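# AMBER-functional-form energies, analytic gradients, interaction
# lists, movable-atom masking.

test_that("assign_types_and_charges types every atom from templates", {
  s <- build_peptide("AA", db = frag_db)
  assign_types_and_charges(s, frag_db)
  expect_false(anyNA(s$atoms$type))
  expect_equal(total_charge(s), 0, tolerance = 1e-6)

  w <- make_water()
  assign_types_and_charges(w, frag_db)
  expect_equal(sort(w$atoms$charge), sort(c(-0.834, 0.417, 0.417)))
  expect_equal(total_charge(w), 0, tolerance = 1e-9)

  bad <- build_peptide("AA", db = frag_db)
  add_atom(bad, 1, "ZZ", "C", c(50, 50, 50))
  expect_error(assign_types_and_charges(bad, frag_db), "ZZ")
})

test_that("build_interactions enumerates the graph exactly", {
  ## ethane: 7 stretches, 12 bends, 9 torsions
  e <- make_ethane()
  li <- build_interactions(e, ff_params)
  expect_equal(nrow(li$stretches), 7)
  expect_equal(nrow(li$bends), 12)
  expect_equal(nrow(unique(li$torsions[c("i", "j", "k", "l")])), 9)

  ## water: 2 stretches, 1 bend, no torsions, no nonbonded pairs
  w <- make_water()
  assign_types_and_charges(w, frag_db)
  lw <- build_interactions(w, ff_params)
  expect_equal(nrow(lw$stretches), 2)
  expect_equal(nrow(lw$bends), 1)
  expect_equal(nrow(lw$torsions), 0)
  expect_equal(nrow(lw$nonbonded), 0)

  ## butane-like chain: the 1-4 pair is scaled, not full
  s <- new_system()
  r <- add_residue(s, add_chain(s, ""), "BUT", 1, het = TRUE)
  for (k in 1:4) add_atom(s, r, paste0("C", k), "C", c(k * 1.5, 0, 0))
  for (k in 1:3) add_bond(s, k, k + 1)
  s$atoms$type <- "CT"
  lb <- build_interactions(s, ff_params)
  p14 <- lb$nonbonded[lb$nonbonded$i == 1 & lb$nonbonded$j == 4, ]
  expect_equal(nrow(p14), 1)
  expect_true(p14$scaled)
  ## 1-2 and 1-3 pairs are excluded entirely
  expect_false(any(lb$nonbonded$i == 1 & lb$nonbonded$j %in% c(2, 3)))

  ## exact determinism
  lb2 <- build_interactions(s, ff_params)
  expect_identical(lb, lb2)

  ## missing parameter names the offending tuple
  s$atoms$type <- c("CT", "CT", "CT", "OW")
  expect_error(build_interactions(s, ff_params), "OW")
})

test_that("energy terms match closed-form values", {
  ## single stretch k=310 r0=1.526 at r=1.626 -> 3.10 kcal/mol
  d <- make_diatomic(stretch = 0.1, k = 310, r0 = 1.526)
  ld <- build_interactions(d, ff_params)
  ld$stretches$k <- 310; ld$stretches$r0 <- 1.526
  e <- compute_energy(ld, coords(d))
  expect_equal(e$stretch, 310 * 0.1^2, tolerance = 1e-9)
  expect_equal(e$total, e$stretch + e$bend + e$torsion + e$vdw +
                 e$electrostatic, tolerance = 1e-12)

  ## two unit charges at 1 A -> -332.0637 kcal/mol
  s <- new_system()
  r <- add_residue(s, add_chain(s, ""), "ION", 1, het = TRUE)
  add_atom(s, r, "NA1", "Na", c(0, 0, 0), charge = 1)
  add_atom(s, r, "CL1", "Cl", c(1, 0, 0), charge = -1)
  li <- list(stretches = data.frame(i = integer(), j = integer(),
                                    k = numeric(), r0 = numeric()),
             bends = data.frame(i = integer(), j = integer(), k = integer(),
                                kth = numeric(), theta0 = numeric()),
             torsions = data.frame(i = integer(), j = integer(),
                                   k = integer(), l = integer(),
                                   vn2 = numeric(), n = numeric(),
                                   gamma = numeric()),
             nonbonded = data.frame(i = 1L, j = 2L, scaled = FALSE,
                                    rmin = 0, eps = 0, qq = -1),
             masses = c(22.99, 35.45), opts = ff_params$opts, natoms = 2L)
  li$opts$cutoff <- 0
  class(li) <- "interaction_lists"
  e <- compute_energy(li, coords(s))
  expect_equal(e$electrostatic, -332.0637, tolerance = 1e-9)

  ## vdW pair at r = rmin -> exactly -eps
  li$nonbonded <- data.frame(i = 1L, j = 2L, scaled = FALSE,
                             rmin = 1.0, eps = 0.25, qq = 0)
  e <- compute_energy(li, coords(s))
  expect_equal(e$vdw, -0.25, tolerance = 1e-12)

  ## torsion term at n*phi - gamma = 180 contributes 0
  tphi <- 180  # trans
  li$nonbonded <- li$nonbonded[0, ]
  li$torsions <- data.frame(i = 1L, j = 2L, k = 3L, l = 4L,
                            vn2 = 2.5, n = 1, gamma = 0)
  li$natoms <- 4L
  xyz <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, -1, 0), c(-1, -1, 0))  # trans
  e <- compute_energy(li, xyz)
  expect_equal(e$torsion, 0, tolerance = 1e-12)

  ## overlapping nonbonded pair is singular
  li$torsions <- li$torsions[0, ]
  li$nonbonded <- data.frame(i = 1L, j = 2L, scaled = FALSE,
                             rmin = 1, eps = 0.1, qq = 0)
  li$natoms <- 2L
  expect_error(compute_energy(li, rbind(c(0, 0, 0), c(0, 0, 1e-8))),
               "singular nonbonded distance")
})

test_that("analytic gradient matches finite differences", {
  set.seed(5)
  seqs <- c("AS", "GG", "SC", "AT")
  for (sq in seqs) {
    s <- build_peptide(sq, phi = stats::runif(1, -150, -50),
                       psi = stats::runif(1, -60, 160), db = frag_db)
    ff <- ff_setup(s, frag_db, ff_params, cutoff = 0)
    xyz <- coords(s)
    g <- compute_gradient(ff, xyz)
    fd <- fd_gradient(ff, xyz)
    expect_lt(max(abs(g - fd) / pmax(1, abs(fd))), 1e-6)
    ## net force vanishes without cutoff
    expect_lt(max(abs(colSums(g))), 1e-8)
    ## translation invariance of the gradient
    g2 <- compute_gradient(ff, sweep(xyz, 2, c(3.2, -1.1, 0.7), `+`))
    expect_lt(max(abs(g - g2)), 1e-8)
  }

  ## isolated stretch+bend at template geometry has zero gradient
  w <- make_water()
  ffw <- ff_setup(w, frag_db, ff_params, cutoff = 0)
  ## strip electrostatics within the molecule: water has no nonbonded
  ## pairs anyway, and template geometry matches the parameters
  g <- compute_gradient(ffw)
  expect_lt(max(abs(g)), 1e-8)
})

test_that("energy is invariant under rigid motion and extensive", {
  s <- build_peptide("ASA", db = frag_db)
  ff <- ff_setup(s, frag_db, ff_params, cutoff = 0)
  e0 <- compute_energy(ff)$total
  set.seed(9)
  xyz <- coords(s)
  for (rep in 1:5) {
    R <- random_rotation()
    t <- stats::rnorm(3, sd = 10)
    moved <- sweep(xyz %*% t(R), 2, t, `+`)
    expect_equal(compute_energy(ff, moved)$total, e0, tolerance = 1e-8)
  }

  ## two far-apart copies double the bonded energies exactly
  w <- make_water(stretch = 0.2)
  ww <- make_water(stretch = 0.2)
  comb <- sys_copy(w)
  ch2 <- add_chain(comb, "X")
  r2 <- add_residue(comb, ch2, "HOH", 2, het = TRUE)
  for (k in seq_len(n_atoms(ww)))
    add_atom(comb, r2, ww$atoms$name[k], ww$atoms$element[k],
             as.numeric(ww$atoms[k, c("x", "y", "z")]) + 100)
  add_bond(comb, 4, 5); add_bond(comb, 4, 6)
  assign_types_and_charges(w, frag_db)
  assign_types_and_charges(comb, frag_db)
  lw <- build_interactions(w, ff_params)
  lc <- build_interactions(comb, ff_params)
  e1 <- compute_energy(lw, coords(w))
  e2 <- compute_energy(lc, coords(comb))
  expect_equal(e2$stretch, 2 * e1$stretch, tolerance = 1e-10)
  expect_equal(e2$bend, 2 * e1$bend, tolerance = 1e-10)
})

test_that("cutoff truncates distant pairs to zero contribution", {
  s <- new_system()
  r <- add_residue(s, add_chain(s, ""), "ION", 1, het = TRUE)
  add_atom(s, r, "C1", "C", c(0, 0, 0), charge = 0.5)
  add_atom(s, r, "C2", "C", c(15, 0, 0), charge = -0.5)
  s$atoms$type <- "CT"
  li <- build_interactions(s, ff_params)  # default cutoff 12 A
  e <- compute_energy(li, coords(s))
  expect_equal(e$electrostatic, 0)
  li$opts$cutoff <- 0
  e <- compute_energy(li, coords(s))
  expect_lt(e$electrostatic, 0)
})

test_that("movable mask follows the selection contract", {
  s <- build_peptide("AS", db = frag_db)
  deselect(s)
  expect_true(all(set_movable_from_selection(s)))
  apply_selection(s, "element(H)")
  m <- set_movable_from_selection(s)
  expect_identical(m, s$atoms$element == "H")

  ## frozen heavy atoms are bit-immobile during minimization
  ff <- ff_setup(s, frag_db, ff_params, cutoff = 0)
  heavy <- which(!ff$movable)
  pre <- coords(s)[heavy, ]
  minimize_conjugate_gradient(s, ff, minimizer_options(max_iterations = 20))
  expect_identical(coords(s)[heavy, ], pre)

  ## all selected behaves exactly like no selection
  s1 <- build_peptide("GS", db = frag_db)
  deselect(s1)
  ff1 <- ff_setup(s1, frag_db, ff_params, cutoff = 0)
  r1 <- minimize_steepest_descent(s1, ff1,
                                  minimizer_options(max_iterations = 15))
  s2 <- build_peptide("GS", db = frag_db)
  apply_selection(s2, "all")
  ff2 <- ff_setup(s2, frag_db, ff_params, cutoff = 0)
  r2 <- minimize_steepest_descent(s2, ff2,
                                  minimizer_options(max_iterations = 15))
  expect_identical(coords(s1), coords(s2))
  expect_equal(r1$final_energy, r2$final_energy, tolerance = 1e-12)
})
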