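# Side-chain rotamers: chi-angle definitions, library loading,
# application via rigid torsion rotation.

## Standard chi torsion atom quadruples. chi1 = N-CA-CB-X, etc.
CHI_ATOMS <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

#' Load a rotamer library
#'
#' File rows: `residue chi1 chi2 chi3 chi4 probability`, unused chi
#' slots given as `.`. Per-residue probabilities must sum to 1 within
#' 1e-6; entries are sorted descending by probability (ties keep file
#' order).
#'
#' @param path library file; default: the bundled illustrative set.
#' @return a named list: residue -> data frame of rotamers.
#' @export
load_rotamer_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rotamers.txt", package = "molkit",
                        mustWork = TRUE)
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  rows <- do.call(rbind, lapply(lines, function(l) {
    f <- strsplit(l, "[[:space:]]+")[[1]]
    chis <- suppressWarnings(as.numeric(f[2:5]))
    data.frame(residue = f[1], chi1 = chis[1], chi2 = chis[2],
               chi3 = chis[3], chi4 = chis[4],
               probability = as.numeric(f[6]), stringsAsFactors = FALSE)
  }))
  lib <- split(rows, rows$residue)
  lib <- lapply(lib, function(df) {
    if (abs(sum(df$probability) - 1) > 1e-6)
      stop("rotamer probabilities for ", df$residue[1], " do not sum to 1")
    df[order(-df$probability), , drop = FALSE]
  })
  lib
}

#' Most likely rotamer for a residue type
#'
#' @param library from [load_rotamer_library()].
#' @param residue_name 3-letter code.
#' @return one rotamer row (maximum probability; ties broken by list
#'   order).
#' @export
most_likely_rotamer <- function(library, residue_name) {
  df <- library[[residue_name]]
  if (is.null(df)) stop("no rotamers for residue ", residue_name)
  df[which.max(df$probability), , drop = FALSE]
}

#' Apply a rotamer to a residue side chain
#'
#' Sets the side-chain chi torsions to the rotamer's angles via rigid
#' rotation, in chi1 -> chiN order. Backbone atoms never move.
#'
#' @param sys a `molsys` with bonds built.
#' @param ri residue row index.
#' @param rotamer a rotamer row (fields chi1..chi4, `NA` = unused), or
#'   a numeric vector of chi angles.
#' @return invisibly, the system.
#' @export
apply_rotamer <- function(sys, ri, rotamer) {
  resname <- sys$residues$name[ri]
  defs <- CHI_ATOMS[[resname]]
  if (is.null(defs)) return(invisible(sys))  # ALA/GLY/PRO: nothing to set
  chis <- if (is.data.frame(rotamer))
    as.numeric(rotamer[1, c("chi1", "chi2", "chi3", "chi4")])
  else as.numeric(c(rotamer, rep(NA, 4)))[1:4]
  for (k in seq_along(defs)) {
    if (k > 4 || is.na(chis[k])) next
    idx <- vapply(defs[[k]], function(nm) find_atom(sys, ri, nm), integer(1))
    if (anyNA(idx))
      stop(sprintf("cannot set chi%d of %s %d: missing atom %s",
                   k, resname, sys$residues$id[ri],
                   paste(defs[[k]][is.na(idx)], collapse = ",")))
    set_dihedral(sys, idx[1], idx[2], idx[3], idx[4], chis[k])
  }
  invisible(sys)
}
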