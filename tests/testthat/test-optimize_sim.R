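# Minimizers, molecular dynamics, quick optimizer, temperature.

stretched_water_ff <- function(stretch = 0.3) {
  s <- make_water(stretch)
  list(sys = s, ff = ff_setup(s, frag_db, ff_params, cutoff = 0))
}

test_that("minimizers start-at-minimum and converge on stretched water", {
  ## exact minimum: zero movement, converged immediately
  d <- make_diatomic(stretch = 0)
  ffd <- ff_setup(d, frag_db, ff_params, cutoff = 0)
  d$atoms$x[2] <- ffd$lists$stretches$r0[1]  # sit exactly at r0
  res <- minimize_steepest_descent(d, ffd, minimizer_options())
  expect_true(res$converged)
  expect_equal(res$iterations, 0)

  finals <- numeric()
  opts <- minimizer_options(max_iterations = 500, grad_tolerance = 1e-3)
  for (m in c("sd", "cg", "lbfgs")) {
    sw <- stretched_water_ff()
    e0 <- compute_energy(sw$ff)$total
    res <- switch(m,
                  sd = minimize_steepest_descent(sw$sys, sw$ff, opts),
                  cg = minimize_conjugate_gradient(sw$sys, sw$ff, opts),
                  lbfgs = minimize_lbfgs(sw$sys, sw$ff, opts))
    expect_true(res$converged, info = m)
    expect_lt(res$final_energy, e0)
    expect_lte(res$final_rms_gradient, opts$grad_tolerance)
    ## monotone non-increasing energy trace over accepted steps
    expect_true(all(diff(res$energy_trace) <= 1e-12), info = m)
    finals[m] <- res$final_energy
  }
  ## the three methods agree on the single-well minimum
  expect_lt(max(finals) - min(finals), 1e-3)
})

test_that("CG with exact line search finishes an n-dim quadratic in n steps", {
  ## literal quadratics f(x) = 0.5 x'Ax - b'x for n = 2..5, SPD A
  set.seed(21)
  for (n in 2:5) {
    M <- matrix(stats::rnorm(n * n), n)
    A <- crossprod(M) + diag(n) * 0.5
    b <- stats::rnorm(n)
    fn <- function(x) 0.5 * sum(x * (A %*% x)) - sum(b * x)
    gr <- function(x) as.numeric(A %*% x - b)
    res <- molkit:::cg_core(fn, gr, rep(0, n),
                            minimizer_options(max_iterations = 50,
                                              grad_tolerance = 1e-5,
                                              line_search = "exact"))
    expect_true(res$converged, info = n)
    expect_lte(res$iterations, n)
    expect_equal(res$x, as.numeric(solve(A, b)), tolerance = 1e-3)
  }
})

test_that("L-BFGS specifics: first step is steepest descent; sy guard", {
  ## empty memory: first direction equals -gradient. Verify by a single
  ## Armijo step agreeing with SD on the same system.
  s1 <- make_water(0.3); f1 <- ff_setup(s1, frag_db, ff_params, cutoff = 0)
  s2 <- make_water(0.3); f2 <- ff_setup(s2, frag_db, ff_params, cutoff = 0)
  o <- minimizer_options(max_iterations = 1)
  minimize_lbfgs(s1, f1, o)
  minimize_steepest_descent(s2, f2, o)
  expect_equal(coords(s1), coords(s2), tolerance = 1e-12)

  ## stretched water converges within the recorded regression budget
  sw <- stretched_water_ff()
  cg <- minimize_conjugate_gradient(
    sw$sys, sw$ff, minimizer_options(max_iterations = 500,
                                     grad_tolerance = 1e-3))
  sw2 <- stretched_water_ff()
  lb <- minimize_lbfgs(sw2$sys, sw2$ff,
                       minimizer_options(max_iterations = 500,
                                         grad_tolerance = 1e-3))
  expect_lte(lb$iterations, cg$iterations + 10)
})

test_that("velocity-Verlet integrates exactly in the ballistic limit", {
  s <- new_system()
  r <- add_residue(s, add_chain(s, ""), "FRE", 1, het = TRUE)
  add_atom(s, r, "C1", "C", c(0, 0, 0))
  s$atoms$type <- "CT"
  li <- build_interactions(s, ff_params)
  ff <- list(sys = s, lists = li, movable = TRUE)
  class(ff) <- "forcefield"
  run_md(s, ff, md_options(timestep = 1, steps = 10, temperature = 0),
         velocities = matrix(c(1, 0, 0), 1))
  expect_equal(as.numeric(coords(s)[1, ]), c(10, 0, 0), tolerance = 1e-12)
})

test_that("MD conserves energy for a small-amplitude harmonic diatomic", {
  run_drift <- function(dt, steps) {
    d <- make_diatomic(stretch = 0.01)
    ff <- ff_setup(d, frag_db, ff_params, cutoff = 0)
    md <- run_md(d, ff, md_options(timestep = dt, steps = steps,
                                   temperature = 0, sample_every = 10),
                 velocities = matrix(0, 2, 3))
    max(md$total) - min(md$total)
  }
  drift1 <- run_drift(0.5, 1000)
  expect_lt(drift1, 1e-4)
  drift2 <- run_drift(0.25, 2000)
  ## halving the timestep shrinks drift roughly 4x (symplectic O(dt^2))
  expect_lt(drift2, drift1 / 2.5)
})

test_that("MD is deterministic by seed and masks frozen atoms", {
  mk <- function() {
    s <- build_peptide("GA", db = frag_db)
    apply_selection(s, "element(H)")
    list(s = s, ff = ff_setup(s, frag_db, ff_params, cutoff = 0))
  }
  a <- mk(); b <- mk()
  ta <- run_md(a$s, a$ff, md_options(steps = 50, seed = 42))
  tb <- run_md(b$s, b$ff, md_options(steps = 50, seed = 42))
  expect_identical(coords(a$s), coords(b$s))
  expect_identical(ta$total, tb$total)
  ## frozen heavy atoms never moved
  heavy <- which(!a$ff$movable)
  ref <- build_peptide("GA", db = frag_db)
  expect_identical(coords(a$s)[heavy, ], coords(ref)[heavy, ])
})

test_that("compute_temperature implements the equipartition definition", {
  expect_equal(compute_temperature(12, matrix(0, 1, 3)), 0)
  ## single atom with KE = 3/2 kB 300
  ke_target <- 1.5 * 0.0019872041 * 300
  v <- sqrt(2 * ke_target * 4.184e-4 / 12)
  expect_equal(compute_temperature(12, matrix(c(v, 0, 0), 1)), 300,
               tolerance = 1e-9)
  expect_error(compute_temperature(numeric(0), matrix(0, 0, 3)), "zero")

  ## Maxwell-Boltzmann sampling statistics: 1000 atoms at 300 K
  masses <- rep(12, 1000)
  set.seed(3)
  sd <- sqrt(0.0019872041 * 300 * 4.184e-4 / masses)
  v <- matrix(stats::rnorm(3000), ncol = 3) * sd
  t_hat <- compute_temperature(masses, v)
  sigma <- 300 * sqrt(2 / (3 * 1000))
  expect_lt(abs(t_hat - 300), 3 * sigma)
})

test_that("quick_optimize keeps the best conformation and is seeded", {
  s0 <- build_peptide("GS", db = frag_db)
  ff0 <- ff_setup(s0, frag_db, ff_params, cutoff = 0)
  opts <- minimizer_options(max_iterations = 100, grad_tolerance = 0.05)
  plain <- minimize_conjugate_gradient(s0, ff0, opts)

  run <- function(seed) {
    s <- build_peptide("GS", db = frag_db)
    ff <- ff_setup(s, frag_db, ff_params, cutoff = 0)
    list(res = quick_optimize(s, ff, rounds = 2, seed = seed, opts = opts),
         xyz = coords(s))
  }
  q1 <- run(7)
  expect_lte(q1$res$final_energy, plain$final_energy + 1e-9)
  q2 <- run(7)
  expect_identical(q1$xyz, q2$xyz)

  ## rounds = 0 is a plain CG minimization
  s <- build_peptide("GS", db = frag_db)
  ff <- ff_setup(s, frag_db, ff_params, cutoff = 0)
  q0 <- quick_optimize(s, ff, rounds = 0, seed = 1, opts = opts)
  expect_equal(q0$final_energy, plain$final_energy, tolerance = 1e-12)
})
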