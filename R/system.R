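# Hierarchical molecular data model.
#
# A molecular system is an environment (reference semantics, like the
# mutable containers in igraph or data.table) holding four aligned
# tables:
#   chains   : id (single character; "" for free molecules)
#   residues : name, id, icode, chain (row index into chains),
#              nterm/cterm flags, het flag
#   atoms    : name, element, x/y/z (Angstrom), charge (partial, e),
#              formal_charge, selected, occupancy, temp_factor,
#              serial, type (force-field type), res (row index into
#              residues)
#   bonds    : i, j (atom row indices, i < j), order (1, 2, 3 or the
#              aromatic marker 1.5)
#
# Row order IS document order: traversal, I/O and all deterministic
# contracts follow insertion order, never serial numbers.

#' Aromatic bond order marker
#'
#' Bond orders are stored numerically; single/double/triple are 1, 2, 3
#' and aromatic (delocalized) bonds carry this sentinel value.
#' @export
BOND_AROMATIC <- 1.5

empty_atoms <- function() {
  data.frame(name = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric(),
             charge = numeric(), formal_charge = integer(),
             selected = logical(), occupancy = numeric(),
             temp_factor = numeric(), serial = integer(),
             type = character(), res = integer(),
             stringsAsFactors = FALSE)
}

empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), order = numeric())
}

#' Create an empty molecular system
#'
#' @return a `molsys` object: a mutable container for a
#'   system -> chain -> residue -> atom hierarchy plus a bond graph.
#' @examples
#' s <- new_system()
#' ch <- add_chain(s, "A")
#' r <- add_residue(s, ch, "GLY", 1)
#' add_atom(s, r, "N", "N", c(0, 0, 0))
#' n_atoms(s)
#' @export
new_system <- function() {
  sys <- new.env(parent = emptyenv())
  sys$chains <- data.frame(id = character(), stringsAsFactors = FALSE)
  sys$residues <- data.frame(name = character(), id = integer(),
                             icode = character(), chain = integer(),
                             nterm = logical(), cterm = logical(),
                             het = logical(), stringsAsFactors = FALSE)
  sys$atoms <- empty_atoms()
  sys$bonds <- empty_bonds()
  class(sys) <- "molsys"
  sys
}

#' @export
print.molsys <- function(x, ...) {
  cat(sprintf("<molsys: %d chain(s), %d residue(s), %d atom(s), %d bond(s)>\n",
              nrow(x$chains), nrow(x$residues), nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Deep-copy a molecular system
#'
#' Produces an independent system: mutating the copy never affects the
#' original.
#' @param sys a `molsys`.
#' @return a new, equal `molsys`.
#' @export
sys_copy <- function(sys) {
  out <- new.env(parent = emptyenv())
  out$chains <- sys$chains
  out$residues <- sys$residues
  out$atoms <- sys$atoms
  out$bonds <- sys$bonds
  class(out) <- "molsys"
  out
}

#' Number of atoms / residues / chains / bonds
#' @param sys a `molsys`.
#' @return integer count.
#' @export
n_atoms <- function(sys) nrow(sys$atoms)

#' @rdname n_atoms
#' @export
n_residues <- function(sys) nrow(sys$residues)

#' @rdname n_atoms
#' @export
n_chains <- function(sys) nrow(sys$chains)

#' @rdname n_atoms
#' @export
n_bonds <- function(sys) nrow(sys$bonds)

#' Add a chain to a system
#'
#' @param sys a `molsys`.
#' @param id single-character chain identifier ("" for a container of
#'   free, non-polymer molecules).
#' @return the row index of the new chain.
#' @export
add_chain <- function(sys, id = "A") {
  sys$chains <- rbind(sys$chains,
                      data.frame(id = as.character(id),
                                 stringsAsFactors = FALSE))
  nrow(sys$chains)
}

#' Add a residue to a chain
#'
#' @param sys a `molsys`.
#' @param chain chain row index from [add_chain()].
#' @param name residue name (3-letter code for polymers).
#' @param id integer residue sequence number.
#' @param icode insertion code ("" when absent).
#' @param het logical: non-polymer (HETATM-style) residue.
#' @return the row index of the new residue.
#' @export
add_residue <- function(sys, chain, name, id = 1L, icode = "", het = FALSE) {
  stopifnot(chain >= 1, chain <= nrow(sys$chains))
  sys$residues <- rbind(sys$residues,
                        data.frame(name = as.character(name),
                                   id = as.integer(id),
                                   icode = as.character(icode),
                                   chain = as.integer(chain),
                                   nterm = FALSE, cterm = FALSE,
                                   het = isTRUE(het),
                                   stringsAsFactors = FALSE))
  nrow(sys$residues)
}

#' Add an atom to a residue
#'
#' @param sys a `molsys`.
#' @param res residue row index from [add_residue()].
#' @param name atom name (up to 4 characters, e.g. "CA").
#' @param element chemical symbol; must be in the bundled periodic table.
#' @param pos numeric 3-vector, Angstrom.
#' @param charge partial charge, elementary charges.
#' @param formal_charge integer formal charge.
#' @param occupancy,temp_factor crystallographic metadata.
#' @param serial original file serial number (I/O metadata only).
#' @return the row index of the new atom.
#' @export
add_atom <- function(sys, res, name, element, pos,
                     charge = 0, formal_charge = 0L,
                     occupancy = 1, temp_factor = 0, serial = NA_integer_) {
  stopifnot(res >= 1, res <= nrow(sys$residues))
  element <- normalize_element(element)
  if (!is_known_element(element))
    stop("unknown element symbol: '", element, "'")
  pos <- as.numeric(pos)
  if (length(pos) != 3 || !all(is.finite(pos)))
    stop("atom position must be a finite 3-vector")
  sys$atoms <- rbind(sys$atoms,
                     data.frame(name = as.character(name), element = element,
                                x = pos[1], y = pos[2], z = pos[3],
                                charge = as.numeric(charge),
                                formal_charge = as.integer(formal_charge),
                                selected = FALSE,
                                occupancy = as.numeric(occupancy),
                                temp_factor = as.numeric(temp_factor),
                                serial = as.integer(serial),
                                type = NA_character_,
                                res = as.integer(res),
                                stringsAsFactors = FALSE))
  nrow(sys$atoms)
}

#' Create a bond between two atoms
#'
#' At most one bond may exist per unordered atom pair; re-adding an
#' existing bond updates its order instead of duplicating it.
#'
#' @param sys a `molsys`.
#' @param i,j atom row indices; must differ.
#' @param order 1, 2, 3 or [BOND_AROMATIC].
#' @return invisibly, the system.
#' @export
add_bond <- function(sys, i, j, order = 1) {
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("cannot bond an atom to itself")
  na <- nrow(sys$atoms)
  if (i < 1 || j < 1 || i > na || j > na)
    stop("bond endpoint outside system")
  if (!order %in% c(1, 2, 3, BOND_AROMATIC))
    stop("bond order must be 1, 2, 3 or BOND_AROMATIC")
  a <- min(i, j); b <- max(i, j)
  hit <- which(sys$bonds$i == a & sys$bonds$j == b)
  if (length(hit)) {
    sys$bonds$order[hit] <- order
  } else {
    sys$bonds <- rbind(sys$bonds, data.frame(i = a, j = b, order = order))
  }
  invisible(sys)
}

#' Bonds incident to an atom
#'
#' @param sys a `molsys`.
#' @param i atom row index.
#' @return integer vector of bond row indices touching atom `i`.
#' @export
atom_bonds <- function(sys, i) {
  which(sys$bonds$i == i | sys$bonds$j == i)
}

#' Bonded neighbours of an atom
#' @param sys a `molsys`.
#' @param i atom row index.
#' @return integer vector of atom row indices bonded to `i`.
#' @export
atom_neighbors <- function(sys, i) {
  b <- sys$bonds
  c(b$j[b$i == i], b$i[b$j == i])
}

#' Atom coordinates as a matrix
#' @param sys a `molsys`.
#' @return n x 3 numeric matrix (Angstrom), rows in document order.
#' @export
coords <- function(sys) {
  cbind(x = sys$atoms$x, y = sys$atoms$y, z = sys$atoms$z)
}

#' Overwrite atom coordinates
#' @param sys a `molsys`.
#' @param xyz n x 3 numeric matrix.
#' @return invisibly, the system.
#' @export
set_coords <- function(sys, xyz) {
  stopifnot(nrow(xyz) == nrow(sys$atoms), ncol(xyz) == 3)
  sys$atoms$x <- xyz[, 1]
  sys$atoms$y <- xyz[, 2]
  sys$atoms$z <- xyz[, 3]
  invisible(sys)
}

#' Atom row indices belonging to a residue
#' @param sys a `molsys`.
#' @param res residue row index.
#' @return integer vector in document order.
#' @export
residue_atoms <- function(sys, res) which(sys$atoms$res == res)

#' Find an atom by name within a residue
#' @param sys a `molsys`.
#' @param res residue row index.
#' @param name atom name.
#' @return atom row index, or `NA` when absent.
#' @export
find_atom <- function(sys, res, name) {
  idx <- which(sys$atoms$res == res & sys$atoms$name == name)
  if (length(idx)) idx[1] else NA_integer_
}

#' Delete atoms and their incident bonds
#'
#' Remaining atom indices are compacted; bond endpoints are remapped so
#' no dangling bonds remain. Residues and chains are kept even when
#' emptied.
#'
#' @param sys a `molsys`.
#' @param idx atom row indices to remove.
#' @return invisibly, the system.
#' @export
delete_atoms <- function(sys, idx) {
  idx <- unique(as.integer(idx))
  if (!length(idx)) return(invisible(sys))
  keep <- setdiff(seq_len(nrow(sys$atoms)), idx)
  remap <- integer(nrow(sys$atoms))
  remap[keep] <- seq_along(keep)
  b <- sys$bonds
  b <- b[!(b$i %in% idx) & !(b$j %in% idx), , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  sys$atoms <- sys$atoms[keep, , drop = FALSE]
  rownames(sys$atoms) <- NULL
  rownames(b) <- NULL
  sys$bonds <- b
  invisible(sys)
}

#' Structural equality of two systems
#'
#' Compares hierarchy, atom fields and bond sets; coordinates compared
#' within `tol` Angstrom.
#' @param a,b `molsys` objects.
#' @param tol coordinate tolerance, Angstrom.
#' @return logical.
#' @export
sys_equal <- function(a, b, tol = 0) {
  if (nrow(a$atoms) != nrow(b$atoms)) return(FALSE)
  if (!identical(a$chains, b$chains)) return(FALSE)
  meta_a <- a$atoms[setdiff(names(a$atoms), c("x", "y", "z"))]
  meta_b <- b$atoms[setdiff(names(b$atoms), c("x", "y", "z"))]
  rownames(meta_a) <- rownames(meta_b) <- NULL
  ra <- a$residues; rb <- b$residues
  rownames(ra) <- rownames(rb) <- NULL
  if (!identical(ra, rb)) return(FALSE)
  if (!identical(meta_a, meta_b)) return(FALSE)
  if (nrow(a$atoms) && max(abs(coords(a) - coords(b))) > tol) return(FALSE)
  ba <- a$bonds[order(a$bonds$i, a$bonds$j), , drop = FALSE]
  bb <- b$bonds[order(b$bonds$i, b$bonds$j), , drop = FALSE]
  rownames(ba) <- rownames(bb) <- NULL
  identical(ba, bb)
}

#' Apply a processor over the hierarchy
#'
#' Visits the system, then every chain, its residues, and their atoms
#' in deterministic depth-first document order (insertion order). The
#' processor may mutate the system; an atom visit returning the string
#' `"delete"` marks that atom for removal after the traversal (bonds
#' are cleaned up with it).
#'
#' @param sys a `molsys`.
#' @param proc `function(kind, sys, index)` where `kind` is one of
#'   `"system"`, `"chain"`, `"residue"`, `"atom"` and `index` is the
#'   row index of the visited node (`NA` for the system itself).
#' @return the (possibly mutated) system, invisibly.
#' @export
apply_processor <- function(sys, proc) {
  stopifnot(is.function(proc))
  to_delete <- integer()
  visit <- function(kind, index) {
    res <- tryCatch(proc(kind, sys, index),
                    error = function(e) {
                      stop(sprintf("processor failed at %s %s: %s", kind,
                                   ifelse(is.na(index), "<root>", index),
                                   conditionMessage(e)), call. = FALSE)
                    })
    if (kind == "atom" && identical(res, "delete"))
      to_delete <<- c(to_delete, index)
    invisible(NULL)
  }
  visit("system", NA_integer_)
  for (ci in seq_len(nrow(sys$chains))) {
    visit("chain", ci)
    for (ri in which(sys$residues$chain == ci)) {
      visit("residue", ri)
      for (ai in which(sys$atoms$res == ri)) visit("atom", ai)
    }
  }
  if (length(to_delete)) delete_atoms(sys, to_delete)
  invisible(sys)
}

#' Net partial charge of a system
#' @param sys a `molsys`.
#' @return sum of atomic partial charges, elementary charges.
#' @export
total_charge <- function(sys) sum(sys$atoms$charge)

#' Mark chain termini
#'
#' Flags the first residue of every polymer chain as N-terminal and the
#' last as C-terminal (both for single-residue chains). Hetero residues
#' (waters, ligands) are skipped.
#' @param sys a `molsys`.
#' @return invisibly, the system.
#' @export
flag_termini <- function(sys) {
  if (!nrow(sys$residues)) return(invisible(sys))
  sys$residues$nterm <- FALSE
  sys$residues$cterm <- FALSE
  for (ci in seq_len(nrow(sys$chains))) {
    ri <- which(sys$residues$chain == ci & !sys$residues$het)
    if (!length(ri)) next
    sys$residues$nterm[ri[1]] <- TRUE
    sys$residues$cterm[ri[length(ri)]] <- TRUE
  }
  invisible(sys)
}
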