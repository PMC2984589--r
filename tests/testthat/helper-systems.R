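# Shared fixture builders. Everything is generated in code; no binary
# fixtures.

frag_db <- load_fragment_db()
ff_params <- load_ff_params()

## A water molecule built from the fragment template; one O-H bond can
## be stretched by `stretch` Angstrom.
make_water <- function(stretch = 0, id = 1L) {
  s <- new_system()
  ch <- add_chain(s, "W")
  r <- add_residue(s, ch, "HOH", id, het = TRUE)
  add_atom(s, r, "O", "O", c(0, 0, 0))
  add_hydrogens(s, frag_db)
  build_bonds(s, frag_db)
  if (stretch != 0) {
    h1 <- find_atom(s, r, "H1")
    xyz <- coords(s)
    xyz[h1, ] <- xyz[h1, ] * (0.96 + stretch) / 0.96
    set_coords(s, xyz)
  }
  s
}

## Ethane-like CH3-CH3 graph with idealized geometry and manual types.
make_ethane <- function() {
  s <- new_system()
  ch <- add_chain(s, "")
  r <- add_residue(s, ch, "ETH", 1L, het = TRUE)
  c1 <- add_atom(s, r, "C1", "C", c(0, 0, 0))
  c2 <- add_atom(s, r, "C2", "C", c(1.526, 0, 0))
  hpos <- list(c(-0.36, 1.03, 0), c(-0.36, -0.51, 0.89),
               c(-0.36, -0.51, -0.89))
  for (k in 1:3) {
    h <- add_atom(s, r, paste0("H1", k), "H", hpos[[k]])
    add_bond(s, c1, h)
    h2 <- add_atom(s, r, paste0("H2", k), "H",
                   c(1.526, 0, 0) - hpos[[k]] * c(1, -1, -1) - c(0.0, 0, 0))
    add_bond(s, c2, h2)
  }
  add_bond(s, c1, c2)
  s$atoms$type <- ifelse(s$atoms$element == "C", "CT", "HC")
  s
}

## Two bonded carbon-like atoms with a single harmonic stretch term:
## the cleanest harmonic diatomic for MD contracts.
make_diatomic <- function(stretch = 0.01, k = 310, r0 = 1.526) {
  s <- new_system()
  ch <- add_chain(s, "")
  r <- add_residue(s, ch, "DIA", 1L, het = TRUE)
  add_atom(s, r, "C1", "C", c(0, 0, 0))
  add_atom(s, r, "C2", "C", c(r0 + stretch, 0, 0))
  add_bond(s, 1, 2)
  s$atoms$type <- "CT"
  s
}

## Random free molecule for I/O round trips: a random tree of heavy
## atoms plus random bond orders and coordinates.
random_molecule <- function(n_atoms = 6, seed = 1) {
  set.seed(seed)
  elements <- sample(c("C", "N", "O", "S", "P", "Cl"), n_atoms,
                     replace = TRUE)
  s <- new_system()
  ch <- add_chain(s, "")
  r <- add_residue(s, ch, "RND", 1L, het = TRUE)
  for (k in seq_len(n_atoms))
    add_atom(s, r, paste0(elements[k], k), elements[k],
             round(stats::runif(3, -40, 40), 3),
             formal_charge = sample(c(0L, 0L, 0L, 1L, -1L), 1))
  for (k in 2:n_atoms)
    add_bond(s, sample(k - 1, 1), k, sample(c(1, 2, 3), 1))
  s
}

## Random multi-chain polymer-like system for PDB round trips.
random_polymer <- function(seed = 1) {
  set.seed(seed)
  s <- new_system()
  n_chain <- sample(1:3, 1)
  for (ci in seq_len(n_chain)) {
    ch <- add_chain(s, LETTERS[ci])
    for (ri in seq_len(sample(1:3, 1))) {
      res <- add_residue(s, ch, sample(c("ALA", "GLY", "SER"), 1), ri)
      for (ak in seq_len(sample(2:4, 1))) {
        nm <- c("N", "CA", "C", "O")[ak]
        add_atom(s, res, nm, c("N", "C", "C", "O")[ak],
                 round(stats::runif(3, -99, 99), 3),
                 occupancy = round(stats::runif(1), 2),
                 temp_factor = round(stats::runif(1, 0, 99), 2))
      }
    }
  }
  if (n_atoms(s) > 1)
    for (k in seq_len(min(4, n_atoms(s) - 1)))
      add_bond(s, k, k + 1)
  s
}

## Random selection expression tree + its text form, for the
## oracle-equivalence property test.
random_sel_expr <- function(depth = 3) {
  preds <- list(c("element", "H"), c("element", "O"), c("element", "C"),
                c("name", "CA"), c("residue", "ALA"), c("chain", "A"),
                c("residueID", "1"))
  gen <- function(d) {
    if (d == 0 || stats::runif(1) < 0.35) {
      if (stats::runif(1) < 0.15) return("all")
      if (stats::runif(1) < 0.15) return("backbone")
      p <- preds[[sample(length(preds), 1)]]
      return(sprintf("%s(%s)", p[1], p[2]))
    }
    op <- sample(c("AND", "OR", "NOT"), 1)
    if (op == "NOT") sprintf("NOT (%s)", gen(d - 1))
    else sprintf("(%s) %s (%s)", gen(d - 1), op, gen(d - 1))
  }
  gen(depth)
}

## Independent per-atom oracle for selection evaluation: operates on
## one atom at a time with plain R logic (no vectorization).
sel_oracle_atom <- function(sys, ai, text) {
  expr <- parse_expression(text)
  ev <- function(node) {
    if (node$op == "AND") return(ev(node$left) && ev(node$right))
    if (node$op == "OR") return(ev(node$left) || ev(node$right))
    if (node$op == "NOT") return(!ev(node$arg))
    a <- sys$atoms[ai, ]
    res <- sys$residues[a$res, ]
    switch(node$kind,
           all = TRUE,
           element = toupper(a$element) == toupper(node$arg),
           name = toupper(a$name) == toupper(node$arg),
           residue = toupper(res$name) == toupper(node$arg),
           chain = toupper(sys$chains$id[res$chain]) == toupper(node$arg),
           residueid = res$id == as.integer(node$arg),
           backbone = a$name %in% c("N", "CA", "C", "O", "OXT", "H", "HA") &&
             !res$het)
  }
  ev(unclass(expr))
}

## Random dipeptide without steric clashes: the finite-difference
## gradient oracle needs smoothness on the scale of h, which collapsed
## conformations (r^-12 walls) violate. Rejection keeps every sampled
## system physically sane.
random_dipeptide <- function(db = frag_db, min_dist = 1.2) {
  repeat {
    sq <- paste(sample(names(molkit:::AA3), 2), collapse = "")
    s <- build_peptide(sq, phi = stats::runif(1, -150, -50),
                       psi = stats::runif(1, -50, 160), db = db)
    dd <- as.matrix(stats::dist(coords(s)))
    dd[cbind(s$bonds$i, s$bonds$j)] <- Inf
    dd[cbind(s$bonds$j, s$bonds$i)] <- Inf
    diag(dd) <- Inf
    if (min(dd) >= min_dist) return(s)
  }
}

## Finite-difference gradient oracle.
fd_gradient <- function(ff, xyz, h = 1e-5) {
  g <- matrix(0, nrow(xyz), 3)
  for (k in seq_len(nrow(xyz))) for (d in 1:3) {
    xp <- xyz; xp[k, d] <- xp[k, d] + h
    xm <- xyz; xm[k, d] <- xm[k, d] - h
    g[k, d] <- (compute_energy(ff, xp)$total -
                compute_energy(ff, xm)$total) / (2 * h)
  }
  g
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## Exhaustive bond-order oracle: minimum-penalty assignment by full
## enumeration over {1,2,3}^n_free.
exhaustive_bond_orders <- function(sys, table = load_penalty_table()) {
  b <- sys$bonds
  el <- sys$atoms$element
  free <- which(el[b$i] != "H" & el[b$j] != "H")
  heavy <- which(el != "H")
  pen_of <- function(orders) {
    total <- 0
    for (a in heavy) {
      vs <- sum(orders[atom_bonds(sys, a)])
      rows <- table[table$element == el[a] &
                    table$charge == sys$atoms$formal_charge[a], , drop = FALSE]
      if (!nrow(rows)) rows <- table[table$element == el[a] &
                                     table$charge == 0L, , drop = FALSE]
      exact <- rows$penalty[rows$valence == vs]
      total <- total + if (length(exact)) min(exact) else
        32L * min(abs(rows$valence - vs))
    }
    total
  }
  orders <- rep(1, nrow(b))
  if (!length(free)) return(list(orders = orders, penalty = pen_of(orders)))
  grid <- expand.grid(rep(list(c(1, 2, 3)), length(free)))
  best <- NULL
  for (row in seq_len(nrow(grid))) {
    orders[free] <- as.numeric(grid[row, ])
    p <- pen_of(orders)
    if (is.null(best) || p < best$penalty)
      best <- list(orders = orders, penalty = p)
  }
  best
}
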