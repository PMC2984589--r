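# Fragment-database driven structure preparation.
#
# The database is a line-oriented text file with sections
#   [residue NAME VARIANT]        VARIANT in internal/n_terminal/c_terminal/free
#   atom NAME ELEMENT TYPE CHARGE REF1 REF2 REF3 LENGTH ANGLE TORSION
#   bond NAMEA NAMEB ORDER
# Reference atoms name earlier template atoms; a leading "-" refers to
# the previous residue in the chain, "." means "no reference" (chain
# seeds, free molecules). TORSION is numeric or one of the symbolic
# backbone angles phi / psi / omega / psi+180 substituted by the
# peptide builder.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

frag_cache <- new.env(parent = emptyenv())

#' Load a fragment database
#'
#' Parses the bundled (or a user-supplied) residue template file:
#' per-residue atoms with ideal internal coordinates, force-field
#' types, partial charges and intra-residue bonds, in four terminal
#' variants. Validation enforces that reference atoms precede the
#' atoms they define and that per-variant charges sum to an integer.
#'
#' @param path template file; default: the bundled amino-acid set
#'   (20 standard residues + water).
#' @param alias_path atom-name alias map file.
#' @return a `fragment_db` list with `templates` and `aliases`.
#' @export
load_fragment_db <- function(path = NULL, alias_path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fragments.txt", package = "molkit",
                        mustWork = TRUE)
  if (is.null(alias_path))
    alias_path <- system.file("extdata", "atom_aliases.txt",
                              package = "molkit", mustWork = TRUE)
  key <- paste(path, alias_path, sep = "|")
  if (!is.null(frag_cache[[key]])) return(frag_cache[[key]])

  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  templates <- list()
  cur <- NULL
  cur_key <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    templates[[cur_key]] <<- validate_template(cur)
  }
  for (line in lines) {
    if (startsWith(line, "[residue")) {
      flush()
      f <- strsplit(gsub("[][]", "", line), "[[:space:]]+")[[1]]
      cur <- list(name = f[2], variant = f[3],
                  atoms = data.frame(name = character(), element = character(),
                                     type = character(), charge = numeric(),
                                     ref1 = character(), ref2 = character(),
                                     ref3 = character(), length = numeric(),
                                     angle = numeric(), torsion = character(),
                                     stringsAsFactors = FALSE),
                  bonds = data.frame(a = character(), b = character(),
                                     order = numeric(),
                                     stringsAsFactors = FALSE))
      cur_key <- paste(f[2], f[3], sep = ".")
      next
    }
    f <- strsplit(line, "[[:space:]]+")[[1]]
    if (f[1] == "atom") {
      cur$atoms <- rbind(cur$atoms, data.frame(
        name = f[2], element = f[3], type = f[4],
        charge = as.numeric(f[5]),
        ref1 = f[6], ref2 = f[7], ref3 = f[8],
        length = as.numeric(f[9]), angle = as.numeric(f[10]),
        torsion = f[11], stringsAsFactors = FALSE))
    } else if (f[1] == "bond") {
      cur$bonds <- rbind(cur$bonds, data.frame(
        a = f[2], b = f[3], order = as.numeric(f[4]),
        stringsAsFactors = FALSE))
    } else stop("bad fragment-db line: ", line)
  }
  flush()

  ## synthesize terminal variants from the internal templates unless a
  ## variant section is supplied explicitly (explicit sections win, so
  ## extended databases can override the derivation)
  for (key in names(templates)) {
    tpl <- templates[[key]]
    if (tpl$variant != "internal") next
    for (v in c("n_terminal", "c_terminal", "free")) {
      vkey <- paste(tpl$name, v, sep = ".")
      if (is.null(templates[[vkey]]))
        templates[[vkey]] <- validate_template(variant_from_internal(tpl, v))
    }
  }

  alines <- readLines(alias_path, warn = FALSE)
  alines <- trimws(sub("#.*$", "", alines))
  alines <- alines[nzchar(alines)]
  aliases <- do.call(rbind, lapply(alines, function(l) {
    f <- strsplit(l, "[[:space:]]+")[[1]]
    data.frame(alias = f[1], canonical = f[2],
               residue = if (length(f) >= 3) f[3] else "",
               stringsAsFactors = FALSE)
  }))
  db <- structure(list(templates = templates, aliases = aliases),
                  class = "fragment_db")
  frag_cache[[key]] <- db
  db
}

## Derive a terminal variant from an internal residue template:
## N-terminal gets a protonated amine (N3 with H1..H3; prolines H1/H2),
## C-terminal a carboxylate (O/OXT as O2); the charge residual is
## spread over side-chain carbons so each variant sums to an exact
## integer at the bundled 6-decimal precision.
variant_from_internal <- function(tpl, variant) {
  at <- tpl$atoms
  bonds <- tpl$bonds
  pro <- tpl$name == "PRO"
  arow <- function(name, element, type, charge, r1, r2, r3, len, ang, tor)
    data.frame(name = name, element = element, type = type,
               charge = charge, ref1 = r1, ref2 = r2, ref3 = r3,
               length = len, angle = ang, torsion = as.character(tor),
               stringsAsFactors = FALSE)

  if (variant %in% c("n_terminal", "free")) {
    at$type[at$name == "N"] <- "N3"
    at$charge[at$name == "N"] <- -0.30
    at[at$name == "N", c("ref1", "ref2", "ref3")] <- "."
    at$torsion[at$name == "N"] <- "0"
    at[at$name == "CA", c("ref2", "ref3")] <- "."
    at$torsion[at$name == "CA"] <- "0"
    at$ref3[at$name == "C"] <- "."
    at$torsion[at$name == "C"] <- "0"
    at <- at[at$name != "H", , drop = FALSE]
    bonds <- bonds[!(bonds$a == "H" | bonds$b == "H"), , drop = FALSE]
    hs <- if (pro) rbind(
      arow("H1", "H", "H", 0.31, "N", "CA", "CD", 1.010, 109.5, 120),
      arow("H2", "H", "H", 0.31, "N", "CA", "CD", 1.010, 109.5, -120))
    else rbind(
      arow("H1", "H", "H", 0.31, "N", "CA", "C", 1.010, 109.5, 180),
      arow("H2", "H", "H", 0.31, "N", "CA", "H1", 1.010, 109.5, 120),
      arow("H3", "H", "H", 0.31, "N", "CA", "H1", 1.010, 109.5, -120))
    at <- rbind(at, hs)
    bonds <- rbind(bonds, data.frame(a = hs$name, b = "N", order = 1))
  }
  if (variant %in% c("c_terminal", "free")) {
    at$type[at$name == "O"] <- "O2"
    at$charge[at$name == "O"] <- -0.80
    at$length[at$name == "O"] <- 1.250
    oxt <- arow("OXT", "O", "O2", -0.80, "C", "CA", "O", 1.250, 117.0, 180)
    opos <- which(at$name == "O")
    at <- rbind(at[seq_len(opos), ], oxt, at[-seq_len(opos), , drop = FALSE])
    bonds$order[(bonds$a == "O" & bonds$b == "C") |
                (bonds$a == "C" & bonds$b == "O")] <- 1
    bonds <- rbind(bonds, data.frame(a = "OXT", b = "C", order = 1))
  }

  target <- tpl$net_charge %||% as.integer(round(sum(tpl$atoms$charge)))
  if (variant %in% c("n_terminal", "free")) target <- target + 1L
  if (variant %in% c("c_terminal", "free")) target <- target - 1L
  backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "HA",
                      "H1", "H2", "H3", "HA2", "HA3")
  carbons <- which(at$element == "C" & !(at$name %in% backbone_names))
  if (!length(carbons)) carbons <- which(at$name == "CA")
  at$charge[carbons] <- at$charge[carbons] +
    (target - sum(at$charge)) / length(carbons)
  at$charge <- round(at$charge, 6)
  at$charge[carbons[1]] <- round(at$charge[carbons[1]] +
                                   (target - sum(at$charge)), 6)
  rownames(at) <- NULL
  rownames(bonds) <- NULL
  list(name = tpl$name, variant = variant, atoms = at, bonds = bonds)
}

validate_template <- function(tpl) {
  at <- tpl$atoms
  if (anyDuplicated(at$name))
    stop("duplicate atom name in template ", tpl$name, " ", tpl$variant)
  for (k in seq_len(nrow(at))) {
    for (r in c(at$ref1[k], at$ref2[k], at$ref3[k])) {
      if (r == "." || startsWith(r, "-")) next
      pos <- match(r, at$name)
      if (is.na(pos) || pos >= k)
        stop(sprintf("template %s %s: reference '%s' does not precede atom %s",
                     tpl$name, tpl$variant, r, at$name[k]))
    }
  }
  net <- sum(at$charge)
  if (abs(net - round(net)) > 1e-6)
    stop(sprintf("template %s %s: charges sum to %.8f, not an integer",
                 tpl$name, tpl$variant, net))
  tpl$net_charge <- as.integer(round(net))
  ## reference 3D coordinates of the isolated template, for bond-length
  ## validation in check_residues()
  tpl$ref_coords <- template_coords(tpl)
  tpl
}

## Build idealized coordinates for a template in isolation: previous-
## residue references are replaced by a synthetic backbone stub.
template_coords <- function(tpl) {
  at <- tpl$atoms
  stub <- list("-N" = c(-2.435, 1.221, 0),
               "-CA" = c(-1.458, 0, 0),
               "-C" = c(0, 0, 0))
  pos <- matrix(NA_real_, nrow(at), 3,
                dimnames = list(at$name, NULL))
  getref <- function(r, fallback_near = NULL) {
    if (r == ".") return(NULL)
    if (startsWith(r, "-")) return(stub[[r]])
    p <- pos[r, ]
    if (anyNA(p)) NULL else p
  }
  for (k in seq_len(nrow(at))) {
    tor <- suppressWarnings(as.numeric(at$torsion[k]))
    if (is.na(tor)) {
      tor <- switch(at$torsion[k],
                    phi = -57, psi = -47, omega = 180, `psi+180` = 133,
                    stop("bad torsion token ", at$torsion[k]))
    }
    p1 <- getref(at$ref1[k]); p2 <- getref(at$ref2[k]); p3 <- getref(at$ref3[k])
    pos[k, ] <- place_with_fallback(p1, p2, p3, at$length[k], at$angle[k], tor)
  }
  pos
}

## NeRF placement tolerating missing references (used for chain seeds
## and for waters): missing ref2/ref3 are replaced by deterministic
## synthetic frame points.
place_with_fallback <- function(p1, p2, p3, length, angle, torsion) {
  if (is.null(p1)) return(c(0, 0, 0))
  if (is.null(p2)) return(p1 + c(length, 0, 0))
  if (is.null(p3)) {
    d <- p1 - p2
    ref <- if (abs(d[3]) < 0.9 * vnorm(d)) c(0, 0, 1) else c(0, 1, 0)
    p3 <- p2 + vcross(d, ref)
  }
  place_atom(p1, p2, p3, length, angle, torsion)
}

frag_template <- function(db, resname, variant) {
  db$templates[[paste(resname, variant, sep = ".")]]
}

residue_variant <- function(sys, ri) {
  r <- sys$residues[ri, ]
  if (r$name == "HOH") return("free")
  if (r$nterm && r$cterm) "free"
  else if (r$nterm) "n_terminal"
  else if (r$cterm) "c_terminal"
  else "internal"
}

#' Normalize atom names against the database alias table
#'
#' Strips padding, rewrites digit-first hydrogen names ("1HB" ->
#' "HB1") and maps aliases (residue-scoped entries take precedence)
#' to canonical template names. Unknown names are left intact; the
#' operation is idempotent.
#'
#' @param sys a `molsys`.
#' @param db a `fragment_db`.
#' @return invisibly, the system.
#' @export
normalize_names <- function(sys, db = load_fragment_db()) {
  nm <- trimws(sys$atoms$name)
  ## "1HB2" style -> "HB21"; applies to hydrogens only
  digit_first <- grepl("^[0-9]H", nm)
  nm[digit_first] <- paste0(substr(nm[digit_first], 2,
                                   nchar(nm[digit_first])),
                            substr(nm[digit_first], 1, 1))
  resname <- sys$residues$name[sys$atoms$res]
  al <- db$aliases
  for (k in seq_along(nm)) {
    hit <- which(al$alias == nm[k] & al$residue == resname[k])
    if (!length(hit)) hit <- which(al$alias == nm[k] & al$residue == "")
    if (length(hit)) nm[k] <- al$canonical[hit[1]]
  }
  sys$atoms$name <- nm
  invisible(sys)
}

resolve_ref <- function(sys, ri, ref) {
  if (ref == ".") return(NA_integer_)
  if (startsWith(ref, "-")) {
    prev <- prev_residue(sys, ri)
    if (is.na(prev)) return(NA_integer_)
    return(find_atom(sys, prev, substring(ref, 2)))
  }
  find_atom(sys, ri, ref)
}

prev_residue <- function(sys, ri) {
  ch <- sys$residues$chain[ri]
  cand <- which(sys$residues$chain == ch & !sys$residues$het)
  pos <- match(ri, cand)
  if (is.na(pos) || pos == 1) NA_integer_ else cand[pos - 1]
}

next_residue <- function(sys, ri) {
  ch <- sys$residues$chain[ri]
  cand <- which(sys$residues$chain == ch & !sys$residues$het)
  pos <- match(ri, cand)
  if (is.na(pos) || pos == length(cand)) NA_integer_ else cand[pos + 1]
}

#' Add missing hydrogens from fragment templates
#'
#' Every template hydrogen absent from a residue is created and placed
#' from its ideal internal coordinates relative to atoms already
#' present; when a torsion reference is unavailable an idealized
#' synthetic frame is used. Heavy atoms and existing hydrogens are
#' never touched.
#'
#' @param sys a `molsys` with normalized names.
#' @param db a `fragment_db`.
#' @return invisibly, the system.
#' @export
add_hydrogens <- function(sys, db = load_fragment_db()) {
  flag_termini(sys)
  for (ri in seq_len(nrow(sys$residues))) {
    tpl <- frag_template(db, sys$residues$name[ri], residue_variant(sys, ri))
    if (is.null(tpl)) {
      warning("add_hydrogens: unknown residue ", sys$residues$name[ri])
      next
    }
    at <- tpl$atoms
    for (k in which(at$element == "H")) {
      if (!is.na(find_atom(sys, ri, at$name[k]))) next
      refs <- lapply(c(at$ref1[k], at$ref2[k], at$ref3[k]), function(r) {
        idx <- resolve_ref(sys, ri, r)
        if (is.na(idx)) NULL else as.numeric(sys$atoms[idx, c("x", "y", "z")])
      })
      if (is.null(refs[[1]])) {
        warning(sprintf("add_hydrogens: cannot place %s in %s %d (no anchor)",
                        at$name[k], sys$residues$name[ri],
                        sys$residues$id[ri]))
        next
      }
      tor <- suppressWarnings(as.numeric(at$torsion[k]))
      if (is.na(tor)) tor <- 0
      pos <- place_with_fallback(refs[[1]], refs[[2]], refs[[3]],
                                 at$length[k], at$angle[k], tor)
      add_atom(sys, ri, at$name[k], "H", pos, charge = at$charge[k])
    }
  }
  invisible(sys)
}

#' Build bonds from fragment templates
#'
#' Creates intra-residue bonds from template name pairs (when both
#' atoms exist), peptide bonds C(i)-N(i+1) between chain-adjacent
#' residues within 2.0 Angstrom, and disulfide bridges SG-SG within
#' 2.5 Angstrom. Existing bonds are never duplicated; the operation is
#' idempotent.
#'
#' @param sys a `molsys` with normalized names.
#' @param db a `fragment_db`.
#' @param peptide_cutoff,disulfide_cutoff distance gates, Angstrom.
#' @return invisibly, the system.
#' @export
build_bonds <- function(sys, db = load_fragment_db(),
                        peptide_cutoff = 2.0, disulfide_cutoff = 2.5) {
  flag_termini(sys)
  for (ri in seq_len(nrow(sys$residues))) {
    tpl <- frag_template(db, sys$residues$name[ri], residue_variant(sys, ri))
    if (is.null(tpl)) next
    for (k in seq_len(nrow(tpl$bonds))) {
      a <- find_atom(sys, ri, tpl$bonds$a[k])
      b <- find_atom(sys, ri, tpl$bonds$b[k])
      if (!is.na(a) && !is.na(b)) add_bond(sys, a, b, tpl$bonds$order[k])
    }
  }
  for (ri in seq_len(nrow(sys$residues))) {
    nxt <- next_residue(sys, ri)
    if (is.na(nxt)) next
    ci <- find_atom(sys, ri, "C")
    nj <- find_atom(sys, nxt, "N")
    if (is.na(ci) || is.na(nj)) next
    d <- measure_distance(as.numeric(sys$atoms[ci, c("x", "y", "z")]),
                          as.numeric(sys$atoms[nj, c("x", "y", "z")]))
    if (d <= peptide_cutoff) add_bond(sys, ci, nj, 1)
  }
  sg <- which(sys$atoms$name == "SG" & sys$atoms$element == "S")
  if (length(sg) > 1) {
    for (a in seq_along(sg)) for (b in seq_len(a - 1)) {
      d <- measure_distance(as.numeric(sys$atoms[sg[a], c("x", "y", "z")]),
                            as.numeric(sys$atoms[sg[b], c("x", "y", "z")]))
      if (d <= disulfide_cutoff) add_bond(sys, sg[a], sg[b], 1)
    }
  }
  invisible(sys)
}

#' Validate residues against fragment templates
#'
#' Produces a report of findings: missing template atoms (error),
#' unknown residues (error), atoms absent from the template (warning),
#' bonded pairs deviating more than `length_tol` from the template
#' distance (warning), residue charge sums off the template integer by
#' more than `charge_tol` e (warning), and non-bonded atom pairs
#' closer than `clash_dist` Angstrom (error).
#'
#' @param sys a `molsys` with normalized names.
#' @param db a `fragment_db`.
#' @param length_tol relative bond-length tolerance (default 0.15).
#' @param charge_tol charge-sum tolerance, e (default 0.05).
#' @param clash_dist clash distance, Angstrom (default 0.5).
#' @return a `check_report` data frame (severity, kind, residue,
#'   message); zero rows when clean.
#' @export
check_residues <- function(sys, db = load_fragment_db(),
                           length_tol = 0.15, charge_tol = 0.05,
                           clash_dist = 0.5) {
  flag_termini(sys)
  findings <- list()
  note <- function(severity, kind, residue, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, kind = kind, residue = residue,
      message = message, stringsAsFactors = FALSE)
  loc <- function(ri) sprintf("%s %s%d%s",
                              sys$residues$name[ri],
                              sys$chains$id[sys$residues$chain[ri]],
                              sys$residues$id[ri], sys$residues$icode[ri])

  for (ri in seq_len(nrow(sys$residues))) {
    tpl <- frag_template(db, sys$residues$name[ri], residue_variant(sys, ri))
    if (is.null(tpl)) {
      note("error", "unknown_residue", loc(ri),
           paste("no template for residue", sys$residues$name[ri]))
      next
    }
    present <- sys$atoms$name[sys$atoms$res == ri]
    missing <- setdiff(tpl$atoms$name, present)
    for (m in missing)
      note("error", "missing_atom", loc(ri), paste("missing atom", m))
    extra <- setdiff(present, tpl$atoms$name)
    for (e in extra)
      note("warning", "unknown_atom", loc(ri),
           paste("atom", e, "not in template"))
    ## bond lengths vs template reference geometry
    for (k in seq_len(nrow(tpl$bonds))) {
      a <- find_atom(sys, ri, tpl$bonds$a[k])
      b <- find_atom(sys, ri, tpl$bonds$b[k])
      if (is.na(a) || is.na(b)) next
      ideal <- vnorm(tpl$ref_coords[tpl$bonds$a[k], ] -
                     tpl$ref_coords[tpl$bonds$b[k], ])
      d <- measure_distance(as.numeric(sys$atoms[a, c("x", "y", "z")]),
                            as.numeric(sys$atoms[b, c("x", "y", "z")]))
      if (abs(d - ideal) / ideal > length_tol)
        note("warning", "bond_length_deviation", loc(ri),
             sprintf("bond %s-%s is %.3f A (template %.3f A)",
                     tpl$bonds$a[k], tpl$bonds$b[k], d, ideal))
    }
    ## peptide-bond length
    nxt <- next_residue(sys, ri)
    if (!is.na(nxt)) {
      ci <- find_atom(sys, ri, "C"); nj <- find_atom(sys, nxt, "N")
      if (!is.na(ci) && !is.na(nj)) {
        bnd <- which(sys$bonds$i == min(ci, nj) & sys$bonds$j == max(ci, nj))
        if (length(bnd)) {
          d <- measure_distance(as.numeric(sys$atoms[ci, c("x", "y", "z")]),
                                as.numeric(sys$atoms[nj, c("x", "y", "z")]))
          if (abs(d - 1.329) / 1.329 > length_tol)
            note("warning", "bond_length_deviation", loc(ri),
                 sprintf("peptide bond C-N is %.3f A (template 1.329 A)", d))
        }
      }
    }
    ## charge sum (only meaningful once charges assigned)
    qs <- sum(sys$atoms$charge[sys$atoms$res == ri])
    if (any(sys$atoms$charge[sys$atoms$res == ri] != 0) &&
        abs(qs - tpl$net_charge) > charge_tol)
      note("warning", "charge_anomaly", loc(ri),
           sprintf("charge sum %.3f, template %d", qs, tpl$net_charge))
  }
  ## clashes: non-bonded pairs closer than clash_dist
  xyz <- coords(sys)
  n <- nrow(xyz)
  if (n > 1) {
    bonded <- paste(sys$bonds$i, sys$bonds$j)
    dd <- as.matrix(stats::dist(xyz))
    close <- which(dd < clash_dist & upper.tri(dd), arr.ind = TRUE)
    for (k in seq_len(nrow(close))) {
      i <- close[k, 1]; j <- close[k, 2]
      if (paste(min(i, j), max(i, j)) %in% bonded) next
      note("error", "atom_clash", loc(sys$atoms$res[i]),
           sprintf("atoms %s and %s are %.3f A apart",
                   sys$atoms$name[i], sys$atoms$name[j], dd[i, j]))
    }
  }
  rep <- if (length(findings)) do.call(rbind, findings) else
    data.frame(severity = character(), kind = character(),
               residue = character(), message = character(),
               stringsAsFactors = FALSE)
  class(rep) <- c("check_report", class(rep))
  rep
}

#' Is a check report clean?
#' @param report a `check_report` from [check_residues()].
#' @return TRUE when the report has no findings.
#' @export
is_clean <- function(report) nrow(report) == 0
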