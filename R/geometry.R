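# Geometry primitives. Angstrom and degrees at every API boundary;
# radians appear only inside the kernels.

#' Euclidean distance between two points
#' @param a,b numeric 3-vectors, Angstrom.
#' @return distance in Angstrom.
#' @export
measure_distance <- function(a, b) {
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  vnorm(as.numeric(a) - as.numeric(b))
}

#' Angle at a vertex
#'
#' @param a,b,c numeric 3-vectors; the angle is measured at vertex `b`.
#' @return angle in degrees, in \[0, 180\].
#' @export
measure_angle <- function(a, b, c) {
  u <- as.numeric(a) - as.numeric(b)
  v <- as.numeric(c) - as.numeric(b)
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) stop("degenerate angle")
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) / DEG
}

#' Torsion (dihedral) angle of four points
#'
#' IUPAC convention: 0 degrees when `a` and `d` are eclipsed (cis),
#' sign by the right-hand rule about the `b -> c` axis; range
#' (-180, 180\].
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return dihedral in degrees.
#' @export
measure_dihedral <- function(a, b, c, d) {
  b1 <- as.numeric(b) - as.numeric(a)
  b2 <- as.numeric(c) - as.numeric(b)
  b3 <- as.numeric(d) - as.numeric(c)
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) stop("undefined torsion")
  m1 <- vcross(n1, b2 / vnorm(b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) / DEG
  wrap_angle(ang)
}

## Rotation matrix about unit axis u by angle radians (Rodrigues).
rotation_matrix <- function(u, angle) {
  u <- u / vnorm(u)
  ct <- cos(angle); st <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

## Atom indices on the d-side of the rotatable bond b-c.
## Errors when b and c remain connected without the bond (ring bond).
moving_side <- function(sys, b, c) {
  nb <- sys$bonds
  keep <- !((nb$i == min(b, c)) & (nb$j == max(b, c)))
  nb <- nb[keep, , drop = FALSE]
  adj <- split(c(nb$j, nb$i), c(nb$i, nb$j))
  seen <- rep(FALSE, nrow(sys$atoms))
  seen[c] <- TRUE
  queue <- c
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (nxt in adj[[as.character(cur)]] %||% integer()) {
      if (!seen[nxt]) { seen[nxt] <- TRUE; queue <- c(queue, nxt) }
    }
  }
  if (seen[b]) stop("cannot rotate ring bond")
  which(seen)
}

#' Set a torsion angle by rigid rotation
#'
#' Rotates all atoms on the `d` side of the bond `b`-`c` rigidly about
#' the axis so that `measure_dihedral(a, b, c, d)` equals `target`.
#' Every other atom is left untouched; bond lengths are preserved
#' exactly (rigid motion).
#'
#' @param sys a `molsys` with the bond `b`-`c` present and acyclic.
#' @param a,b,c,d atom row indices defining the torsion.
#' @param target desired dihedral, degrees.
#' @return invisibly, the system.
#' @export
set_dihedral <- function(sys, a, b, c, d, target) {
  xyz <- coords(sys)
  cur <- measure_dihedral(xyz[a, ], xyz[b, ], xyz[c, ], xyz[d, ])
  delta <- wrap_angle(target - cur)
  side <- moving_side(sys, b, c)
  if (abs(delta) < 1e-13) return(invisible(sys))
  axis <- xyz[c, ] - xyz[b, ]
  R <- rotation_matrix(axis, delta * DEG)
  origin <- xyz[b, ]
  moved <- sweep(xyz[side, , drop = FALSE], 2, origin)
  xyz[side, ] <- sweep(moved %*% t(R), 2, origin, `+`)
  set_coords(sys, xyz)
  invisible(sys)
}

#' Place a point from internal coordinates (NeRF)
#'
#' Returns the position at distance `length` from `p1`, forming the
#' given `angle` at `p1` with `p2`, and the given `torsion`
#' `dihedral(p3, p2, p1, new)`.
#'
#' @param p1,p2,p3 reference positions (bonded, angle, torsion).
#' @param length bond length, Angstrom.
#' @param angle bond angle, degrees.
#' @param torsion dihedral, degrees.
#' @return numeric 3-vector.
#' @export
place_atom <- function(p1, p2, p3, length, angle, torsion) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  ang <- angle * DEG
  tor <- torsion * DEG
  d <- c(-length * cos(ang),
         length * sin(ang) * cos(tor),
         length * sin(ang) * sin(tor))
  bc <- p1 - p2
  bc <- bc / vnorm(bc)
  ab <- p2 - p3
  n <- vcross(ab, bc)
  nn <- vnorm(n)
  if (nn < 1e-10) stop("collinear reference atoms in internal-coordinate placement")
  n <- n / nn
  m <- vcross(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(p1 + M %*% d)
}
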