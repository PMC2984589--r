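# Structure analysis: geometric hydrogen-bond detection, the
# electrostatic backbone H-bond energy model, a three-state (H/E/C)
# secondary-structure assignment, and Kabsch superposition RMSD.

#' Detect hydrogen bonds geometrically
#'
#' Donor = N/O/S with an attached hydrogen; acceptor = N/O (not the
#' donor itself). A hydrogen bond is recorded when the donor-acceptor
#' distance is at most `dist_cutoff` and the D-H...A angle is at least
#' `angle_cutoff`. Output order follows donor traversal order.
#'
#' @param sys a `molsys` with hydrogens and bonds present.
#' @param dist_cutoff maximum D...A distance, Angstrom.
#' @param angle_cutoff minimum D-H...A angle, degrees.
#' @return data frame: donor, hydrogen, acceptor (atom indices),
#'   distance (Angstrom), angle (degrees).
#' @export
detect_hydrogen_bonds <- function(sys, dist_cutoff = 3.5,
                                  angle_cutoff = 120) {
  el <- sys$atoms$element
  xyz <- coords(sys)
  acceptors <- which(el %in% c("N", "O"))
  out <- list()
  for (d in which(el %in% c("N", "O", "S"))) {
    hyds <- atom_neighbors(sys, d)
    hyds <- hyds[el[hyds] == "H"]
    if (!length(hyds)) next
    for (a in acceptors) {
      if (a == d) next
      if (a %in% atom_neighbors(sys, d)) next  # covalently bonded pair
      dda <- vnorm(xyz[d, ] - xyz[a, ])
      if (dda > dist_cutoff) next
      for (h in sort(hyds)) {
        ang <- measure_angle(xyz[d, ], xyz[h, ], xyz[a, ])
        if (ang >= angle_cutoff) {
          out[[length(out) + 1L]] <- data.frame(
            donor = d, hydrogen = h, acceptor = a,
            distance = dda, angle = ang)
          break  # one bond per donor/acceptor pair
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  do.call(rbind, out)
}

#' Electrostatic backbone hydrogen-bond energy
#'
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol for
#' an amide donor (N, H) and carbonyl acceptor (C, O); a hydrogen bond
#' is declared when E < -0.5 kcal/mol. Any inter-atom distance below
#' 0.5 Angstrom yields the clash sentinel -9.9.
#'
#' @param n_pos,h_pos donor backbone N and amide H positions.
#' @param c_pos,o_pos acceptor backbone C and carbonyl O positions.
#' @return energy, kcal/mol.
#' @export
backbone_hbond_energy <- function(n_pos, h_pos, c_pos, o_pos) {
  r_on <- vnorm(o_pos - n_pos)
  r_ch <- vnorm(c_pos - h_pos)
  r_oh <- vnorm(o_pos - h_pos)
  r_cn <- vnorm(c_pos - n_pos)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(-9.9)
  0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

## Backbone H-bond matrix: hb[i, j] TRUE when the amide of residue i
## donates to the carbonyl of residue j (Kabsch-Sander energy below
## -0.5 kcal/mol).
backbone_hbond_set <- function(sys, energy_cutoff = -0.5) {
  nres <- n_residues(sys)
  xyz <- coords(sys)
  get <- function(ri, nm) {
    idx <- find_atom(sys, ri, nm)
    if (is.na(idx)) NULL else xyz[idx, ]
  }
  hb <- matrix(FALSE, nres, nres)
  for (i in seq_len(nres)) {
    np <- get(i, "N"); hp <- get(i, "H")
    if (is.null(np) || is.null(hp)) next
    for (j in seq_len(nres)) {
      if (abs(i - j) < 2) next
      cp <- get(j, "C"); op <- get(j, "O")
      if (is.null(cp) || is.null(op)) next
      if (backbone_hbond_energy(np, hp, cp, op) < energy_cutoff)
        hb[i, j] <- TRUE
    }
  }
  hb
}

#' Assign three-state secondary structure
#'
#' Backbone hydrogen bonds come from the electrostatic energy model
#' ([backbone_hbond_energy()], threshold -0.5 kcal/mol). A 4-turn at
#' residue i exists when the amide of i+4 donates to the carbonyl of
#' i; two consecutive 4-turns make residues i+1..i+4 helical (H).
#' Bridges (parallel or antiparallel H-bond patterns between residues
#' more than two apart) mark both partners as strand (E); helix takes
#' precedence. Everything else, including residues missing backbone
#' atoms, is coil (C).
#'
#' @param sys a prepared `molsys` (backbone complete with amide H).
#' @return character vector, one of "H", "E", "C" per residue.
#' @export
assign_secondary_structure <- function(sys) {
  nres <- n_residues(sys)
  state <- rep("C", nres)
  if (nres < 3) return(state)
  hb <- backbone_hbond_set(sys)
  donates <- function(i, j) {
    i >= 1 && j >= 1 && i <= nres && j <= nres && hb[i, j]
  }
  ## 4-turns: amide of i+4 -> carbonyl of i
  turn4 <- vapply(seq_len(nres), function(i) donates(i + 4, i), logical(1))
  helical <- rep(FALSE, nres)
  for (i in seq_len(nres - 1)) {
    if (turn4[i] && (i + 1 <= nres) && turn4[i + 1]) {
      helical[(i + 1):min(i + 4, nres)] <- TRUE
    }
  }
  ## bridges
  strand <- rep(FALSE, nres)
  for (i in seq_len(nres)) for (j in seq_len(nres)) {
    if (abs(i - j) <= 2) next
    parallel <- donates(i, j - 1) && donates(j + 1, i)
    antiparallel <- donates(i, j) && donates(j, i)
    if (parallel || antiparallel) {
      strand[i] <- TRUE; strand[j] <- TRUE
    }
  }
  state[strand] <- "E"
  state[helical] <- "H"  # helix precedence
  state
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Removes centroids, computes the optimal rotation by SVD (with
#' reflection guard), and returns the root-mean-square deviation of
#' the matched atoms.
#'
#' @param xyz_a,xyz_b n x 3 coordinate matrices (or `molsys` objects),
#'   matched row by row, n >= 3.
#' @return RMSD, Angstrom.
#' @export
compute_rmsd <- function(xyz_a, xyz_b) {
  if (inherits(xyz_a, "molsys")) xyz_a <- coords(xyz_a)
  if (inherits(xyz_b, "molsys")) xyz_b <- coords(xyz_b)
  stopifnot(nrow(xyz_a) == nrow(xyz_b))
  if (nrow(xyz_a) < 3) stop("RMSD needs at least 3 matched atoms")
  a <- sweep(xyz_a, 2, colMeans(xyz_a))
  b <- sweep(xyz_b, 2, colMeans(xyz_b))
  s <- svd(t(a) %*% b)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  rot <- a %*% t(R)
  sqrt(mean(rowSums((rot - b)^2)))
}
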