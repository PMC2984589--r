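# SMILES subset reader: organic-subset atoms (B C N O P S F Cl Br I),
# bracket atoms with charge and explicit H count, bonds - = #,
# branches, ring closures (digits and %nn), lowercase aromatic atoms.
# No stereo, no isotopes. Molecules are returned as graphs (no
# coordinates); aromatic input is kekulized and implicit hydrogens are
# materialized.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

#' Default valences used for implicit-hydrogen filling
#'
#' @param element symbol.
#' @param formal_charge integer.
#' @return the target valence (bond-order sum + H count).
#' @keywords internal
default_valence <- function(element, formal_charge = 0L) {
  base <- switch(element,
                 H = 1, B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                 F = 1, Cl = 1, Br = 1, I = 1,
                 stop("no default valence for element ", element))
  ## charge adjustment: cations of N/O gain a bond slot, anions lose one
  if (element %in% c("N", "O", "P", "S")) base + formal_charge
  else base
}

#' Parse a SMILES string (subset grammar)
#'
#' Builds the molecular graph, kekulizes aromatic input, and fills
#' implicit hydrogens via [fill_valence()]. Stereochemistry and
#' isotopes are rejected as unsupported.
#'
#' @param text SMILES string.
#' @param add_hydrogens fill implicit hydrogens (default TRUE).
#' @return a `molsys` without coordinates (all atoms at the origin is
#'   avoided by spreading atoms on a line; geometry is NOT meaningful).
#' @export
parse_smiles <- function(text, add_hydrogens = TRUE) {
  sys <- new_system()
  ch <- add_chain(sys, "")
  res <- add_residue(sys, ch, "UNL", 1L, het = TRUE)

  n <- nchar(text)
  i <- 1
  prev <- NA_integer_          # previous atom index
  stack <- integer()           # branch stack
  pending_bond <- NA_real_     # explicit bond token for the next edge
  ring <- new.env(parent = emptyenv())  # closure digit -> (atom, bond)
  aromatic_atom <- logical()
  explicit_h <- integer()      # bracket-specified H counts (-1 = free)
  count <- 0L

  err <- function(msg, at = i)
    stop(sprintf("SMILES error at offset %d: %s", at, msg))

  new_atom <- function(element, aromatic, charge, hcount) {
    count <<- count + 1L
    add_atom(sys, res, paste0(element, count), element,
             c(count * 1.5, 0, 0), formal_charge = charge)
    aromatic_atom[count] <<- aromatic
    explicit_h[count] <<- hcount
    count
  }
  connect <- function(a, b, order) {
    if (is.na(order)) {
      order <- if (aromatic_atom[a] && aromatic_atom[b]) BOND_AROMATIC else 1
    }
    add_bond(sys, a, b, order)
  }
  handle_ring <- function(digit) {
    key <- as.character(digit)
    open <- ring[[key]]
    if (is.null(open)) {
      ring[[key]] <- list(atom = prev, bond = pending_bond)
    } else {
      order <- pending_bond
      if (is.na(order)) order <- open$bond
      if (open$atom == prev) err("ring closure bonds an atom to itself")
      connect(open$atom, prev, order)
      rm(list = key, envir = ring)
    }
    pending_bond <<- NA_real_
  }

  while (i <= n) {
    c1 <- substr(text, i, i)
    c2 <- substr(text, i, i + 1)
    if (c1 %in% c("/", "\\", "@")) err("unsupported SMILES feature (stereo)")
    if (c1 == "-" && !is.na(prev)) { pending_bond <- 1; i <- i + 1; next }
    if (c1 == "=") { pending_bond <- 2; i <- i + 1; next }
    if (c1 == "#") { pending_bond <- 3; i <- i + 1; next }
    if (c1 == ":") { pending_bond <- BOND_AROMATIC; i <- i + 1; next }
    if (c1 == "(") {
      if (is.na(prev)) err("branch with no preceding atom")
      stack <- c(stack, prev); i <- i + 1; next
    }
    if (c1 == ")") {
      if (!length(stack)) err("unbalanced parenthesis")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1; next
    }
    if (grepl("^[0-9]$", c1)) {
      if (is.na(prev)) err("ring closure with no preceding atom")
      handle_ring(c1); i <- i + 1; next
    }
    if (c1 == "%") {
      dd <- substr(text, i + 1, i + 2)
      if (!grepl("^[0-9][0-9]$", dd)) err("bad %nn ring closure")
      handle_ring(dd); i <- i + 3; next
    }
    if (c1 == "[") {
      close <- regexpr("]", substr(text, i, n), fixed = TRUE)
      if (close < 0) err("unclosed bracket atom")
      body <- substr(text, i + 1, i + close - 2)
      m <- regexec("^([A-Za-z][a-z]?)(H([0-9]?))?([+-]+[0-9]*|[+-][0-9]*)?$",
                   body)[[1]]
      if (m[1] < 0 || grepl("^[0-9]", body))
        err(paste0("unsupported SMILES feature in bracket [", body, "]"))
      parts <- regmatches(body, regexec(
        "^([A-Za-z][a-z]?)(H([0-9]*))?([+-][0-9]*|[+-]+)?$", body))[[1]]
      if (!nzchar(parts[2])) err("bad bracket atom")
      raw_el <- parts[2]
      aromatic <- raw_el %in% c("b", "c", "n", "o", "p", "s")
      element <- normalize_element(raw_el)
      if (!element %in% ORGANIC_SUBSET) err(paste("unsupported element", element))
      hcount <- if (nzchar(parts[3])) {
        if (nzchar(parts[4])) as.integer(parts[4]) else 1L
      } else 0L
      charge <- 0L
      if (nzchar(parts[5])) {
        cs <- parts[5]
        if (grepl("^[+-][0-9]+$", cs)) {
          charge <- as.integer(cs)
        } else {
          charge <- sum(ifelse(strsplit(cs, "")[[1]] == "+", 1L, -1L))
        }
      }
      a <- new_atom(element, aromatic, charge, hcount)
      if (!is.na(prev)) connect(prev, a, pending_bond)
      pending_bond <- NA_real_
      prev <- a
      i <- i + close
      next
    }
    ## organic-subset atom, aromatic lowercase or two-letter halogen
    matched <- NULL
    if (c2 %in% c("Cl", "Br")) { matched <- c2; aromatic <- FALSE }
    else if (c1 %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      matched <- c1; aromatic <- FALSE
    } else if (c1 %in% c("b", "c", "n", "o", "p", "s")) {
      matched <- toupper(c1); aromatic <- TRUE
    }
    if (is.null(matched)) err(paste0("unexpected character '", c1, "'"))
    a <- new_atom(matched, aromatic, 0L, -1L)
    if (!is.na(prev)) connect(prev, a, pending_bond)
    pending_bond <- NA_real_
    prev <- a
    i <- i + nchar(matched)
  }
  if (length(stack)) err("unbalanced parenthesis", n)
  open_digits <- ls(ring)
  if (length(open_digits))
    err(paste("unclosed ring closure digit(s):",
              paste(open_digits, collapse = ", ")), n)

  ## aromatic NH (pyrrole-type) from bracket [nH]: remember explicit H
  attr(sys, "explicit_h") <- explicit_h
  if (any(sys$bonds$order == BOND_AROMATIC)) kekulize(sys)
  if (add_hydrogens) fill_valence(sys, explicit_h)
  sys
}

#' Materialize implicit hydrogens
#'
#' For each heavy atom, adds `default_valence(element, charge) -
#' bond-order sum` hydrogens (floor 0). Atoms whose H count was given
#' explicitly in brackets receive exactly that many.
#'
#' @param sys a `molsys` with definite bond orders (no aromatic
#'   markers).
#' @param explicit_h optional integer vector: bracket H counts per
#'   heavy atom (-1 = not specified).
#' @return invisibly, the system.
#' @export
fill_valence <- function(sys, explicit_h = NULL) {
  if (any(sys$bonds$order == BOND_AROMATIC))
    stop("fill_valence requires kekulized bond orders")
  heavy <- which(sys$atoms$element != "H")
  res <- if (nrow(sys$residues)) 1L else add_residue(sys, add_chain(sys, ""), "UNL")
  hn <- 0L
  for (a in heavy) {
    bsum <- sum(sys$bonds$order[atom_bonds(sys, a)])
    nh <- if (!is.null(explicit_h) && length(explicit_h) >= a &&
              !is.na(explicit_h[a]) && explicit_h[a] >= 0) {
      explicit_h[a]
    } else {
      max(0, default_valence(sys$atoms$element[a],
                             sys$atoms$formal_charge[a]) - bsum)
    }
    base <- as.numeric(sys$atoms[a, c("x", "y", "z")])
    for (k in seq_len(nh)) {
      hn <- hn + 1L
      add_atom(sys, sys$atoms$res[a], paste0("H", hn), "H",
               base + c(0.3 * k, 1.0, 0))
      add_bond(sys, a, nrow(sys$atoms), 1)
    }
  }
  invisible(sys)
}
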