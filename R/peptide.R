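# Peptide construction from sequence + backbone torsions, by
# sequential internal-coordinate (NeRF) placement of fragment-template
# atoms.

#' Build a peptide from sequence and backbone torsions
#'
#' Extends a chain residue by residue: every atom is placed from its
#' template bond length, bond angle and torsion relative to three
#' previously placed reference atoms. Backbone torsions are
#' substituted from the supplied phi/psi/omega values (omega defaults
#' to 180 degrees, trans); side chains and hydrogens come from the
#' template's ideal geometry. Bonds are built, terminal variants
#' applied (first residue N-terminal, last C-terminal, single residue
#' free), and partial charges/types assigned from the templates.
#'
#' @param sequence one-letter amino-acid string (20 standard letters).
#' @param phi,psi backbone torsions, degrees; scalars broadcast to all
#'   residues, or vectors of length `nchar(sequence)`. phi of the
#'   first and psi of the last residue are geometrically undefined and
#'   ignored.
#' @param omega peptide-bond torsion preceding each residue, degrees
#'   (default 180).
#' @param chain_id chain identifier.
#' @param db a `fragment_db`.
#' @return a `molsys`.
#' @examples
#' db <- load_fragment_db()
#' helix <- build_peptide("AAAA", phi = -57, psi = -47, db = db)
#' n_residues(helix)
#' @export
build_peptide <- function(sequence, phi = -57, psi = -47, omega = 180,
                          chain_id = "A", db = load_fragment_db()) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  n <- length(letters1)
  if (!n) stop("empty sequence")
  bad <- which(!letters1 %in% names(AA3))
  if (length(bad))
    stop(sprintf("unknown amino-acid letter '%s' at position %d",
                 letters1[bad[1]], bad[1]))
  rec <- function(v) {
    v <- wrap_angle(as.numeric(v))
    if (length(v) == 1) rep(v, n)
    else if (length(v) == n) v
    else stop("torsion vector length must be 1 or the sequence length")
  }
  phi <- rec(phi); psi <- rec(psi); omega <- rec(omega)

  sys <- new_system()
  ch <- add_chain(sys, chain_id)
  for (i in seq_len(n)) {
    resname <- AA3[[letters1[i]]]
    variant <- if (n == 1) "free"
      else if (i == 1) "n_terminal"
      else if (i == n) "c_terminal"
      else "internal"
    tpl <- frag_template(db, resname, variant)
    if (is.null(tpl)) stop("no template for ", resname, " ", variant)
    ri <- add_residue(sys, ch, resname, i)
    at <- tpl$atoms
    for (k in seq_len(nrow(at))) {
      tor <- suppressWarnings(as.numeric(at$torsion[k]))
      if (is.na(tor)) {
        tor <- switch(at$torsion[k],
                      ## N(i) is placed with the psi of residue i-1;
                      ## CA(i) with the omega of the bond into residue i;
                      ## C(i) with phi(i); O(i) trans to the next N.
                      phi = phi[i],
                      psi = if (at$name[k] == "N") psi[i - 1] else psi[i],
                      omega = omega[i],
                      `psi+180` = wrap_angle(psi[i] + 180),
                      stop("bad torsion token ", at$torsion[k]))
      }
      refs <- lapply(c(at$ref1[k], at$ref2[k], at$ref3[k]), function(r) {
        idx <- resolve_ref(sys, ri, r)
        if (is.na(idx)) NULL else as.numeric(sys$atoms[idx, c("x", "y", "z")])
      })
      pos <- place_with_fallback(refs[[1]], refs[[2]], refs[[3]],
                                 at$length[k], at$angle[k], tor)
      add_atom(sys, ri, at$name[k], at$element[k], pos,
               charge = at$charge[k])
      ai <- nrow(sys$atoms)
      sys$atoms$type[ai] <- at$type[k]
    }
  }
  flag_termini(sys)
  build_bonds(sys, db)
  sys
}

#' Strip hydrogens from a system
#'
#' Convenience for preparation tests and pipelines: removes every
#' hydrogen atom (and its bonds).
#' @param sys a `molsys`.
#' @return invisibly, the system.
#' @export
strip_hydrogens <- function(sys) {
  delete_atoms(sys, which(sys$atoms$element == "H"))
  invisible(sys)
}
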