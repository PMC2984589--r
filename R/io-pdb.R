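# PDB coordinate-section reader/writer (wwPDB v3.3 subset:
# ATOM/HETATM/TER/CONECT/END; HEADER-type records ignored).

#' PDB parse options
#'
#' @param keep_hetero keep HETATM records (default TRUE).
#' @param altloc_policy `"highest_occupancy"` (ties broken by file
#'   order) or `"first"`.
#' @param strict error on malformed records instead of skipping them.
#' @return an options list used by [read_pdb()].
#' @export
pdb_options <- function(keep_hetero = TRUE,
                        altloc_policy = c("highest_occupancy", "first"),
                        strict = FALSE) {
  list(keep_hetero = isTRUE(keep_hetero),
       altloc_policy = match.arg(altloc_policy),
       strict = isTRUE(strict))
}

## Accepts a path, a connection, a single string with newlines, or a
## character vector of lines.
source_lines <- function(source) {
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  if (is.character(source)) {
    if (length(source) == 1 && !grepl("\n", source, fixed = TRUE) &&
        file.exists(source))
      return(readLines(source, warn = FALSE))
    if (length(source) == 1) return(strsplit(source, "\n", fixed = TRUE)[[1]])
    return(source)
  }
  stop("unsupported source type")
}

substr_field <- function(line, from, to) {
  n <- nchar(line)
  if (from > n) return("")
  trimws(substr(line, from, min(to, n)))
}

parse_coord <- function(s) {
  v <- suppressWarnings(as.numeric(s))
  v
}

#' Read a PDB file
#'
#' Builds one residue per (chainID, resSeq, iCode) in file order; TER
#' closes a chain; CONECT records become (deduplicated) bonds; element
#' comes from columns 77-78, falling back to the leading letters of the
#' atom name. Alternate locations are collapsed according to
#' `opts$altloc_policy`.
#'
#' @param source path, connection, or text.
#' @param opts see [pdb_options()].
#' @return a `molsys`.
#' @export
read_pdb <- function(source, opts = pdb_options()) {
  lines <- source_lines(source)
  sys <- new_system()
  cur_chain <- NA_integer_
  cur_chain_id <- NULL
  cur_res <- NA_integer_
  cur_res_key <- NULL
  chain_closed <- FALSE
  serial_map <- new.env(parent = emptyenv())
  ## altloc bookkeeping: atom-site key -> atom row + best occupancy
  alt_seen <- new.env(parent = emptyenv())
  conect <- list()

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    rec <- toupper(substr_field(line, 1, 6))
    if (rec == "TER") {
      chain_closed <- TRUE
      next
    }
    if (rec == "END" || rec == "ENDMDL") break
    if (rec == "CONECT") {
      base <- suppressWarnings(as.integer(substr_field(line, 7, 11)))
      if (is.na(base)) next
      for (fld in list(c(12, 16), c(17, 21), c(22, 26), c(27, 31))) {
        other <- suppressWarnings(as.integer(substr_field(line, fld[1], fld[2])))
        if (!is.na(other)) conect[[length(conect) + 1L]] <- c(base, other)
      }
      next
    }
    if (rec != "ATOM" && rec != "HETATM") next
    is_het <- rec == "HETATM"
    if (is_het && !opts$keep_hetero) next

    name <- substr_field(line, 13, 16)
    altloc <- substr_field(line, 17, 17)
    resname <- substr_field(line, 18, 20)
    chain_id <- substr_field(line, 22, 22)
    resseq <- suppressWarnings(as.integer(substr_field(line, 23, 26)))
    icode <- substr_field(line, 27, 27)
    x <- parse_coord(substr_field(line, 31, 38))
    y <- parse_coord(substr_field(line, 39, 46))
    z <- parse_coord(substr_field(line, 47, 54))
    occ <- parse_coord(substr_field(line, 55, 60))
    bfac <- parse_coord(substr_field(line, 61, 66))
    elem <- substr_field(line, 77, 78)
    serial <- suppressWarnings(as.integer(substr_field(line, 7, 11)))

    if (anyNA(c(x, y, z)) || is.na(resseq)) {
      if (opts$strict)
        stop(sprintf("PDB parse error at line %d: bad coordinate or resSeq field", ln))
      message(sprintf("skipping malformed PDB record at line %d", ln))
      next
    }
    if (is.na(occ)) occ <- 1
    if (is.na(bfac)) bfac <- 0
    if (elem == "") {
      letters_only <- gsub("[^A-Za-z]", "", name)
      two <- normalize_element(substr(letters_only, 1, 2))
      one <- normalize_element(substr(letters_only, 1, 1))
      elem <- if (is_het && nchar(letters_only) >= 2 && is_known_element(two))
        two else one
    } else {
      elem <- normalize_element(elem)
    }
    if (!is_known_element(elem)) {
      if (opts$strict)
        stop(sprintf("PDB parse error at line %d: unknown element '%s'", ln, elem))
      message(sprintf("skipping atom with unknown element at line %d", ln))
      next
    }

    if (is.null(cur_chain_id) || !identical(cur_chain_id, chain_id) ||
        chain_closed) {
      cur_chain <- add_chain(sys, chain_id)
      cur_chain_id <- chain_id
      chain_closed <- FALSE
      cur_res_key <- NULL
    }
    res_key <- paste(chain_id, resseq, icode, sep = "\r")
    if (!identical(res_key, cur_res_key)) {
      cur_res <- add_residue(sys, cur_chain, resname, resseq, icode,
                             het = is_het)
      cur_res_key <- res_key
    }

    site_key <- paste(res_key, name, sep = "\r")
    prev <- alt_seen[[site_key]]
    if (!is.null(prev) && nzchar(altloc)) {
      ## alternate location of an atom already stored
      if (opts$altloc_policy == "highest_occupancy" && occ > prev$occ) {
        sys$atoms$x[prev$row] <- x
        sys$atoms$y[prev$row] <- y
        sys$atoms$z[prev$row] <- z
        sys$atoms$occupancy[prev$row] <- occ
        sys$atoms$temp_factor[prev$row] <- bfac
        alt_seen[[site_key]] <- list(row = prev$row, occ = occ)
        if (!is.na(serial))
          serial_map[[as.character(serial)]] <- prev$row
      }
      next
    }
    row <- add_atom(sys, cur_res, name, elem, c(x, y, z),
                    occupancy = occ, temp_factor = bfac,
                    serial = if (is.na(serial)) NA_integer_ else serial)
    alt_seen[[site_key]] <- list(row = row, occ = occ)
    if (!is.na(serial)) serial_map[[as.character(serial)]] <- row
  }

  for (pair in conect) {
    a <- serial_map[[as.character(pair[1])]]
    b <- serial_map[[as.character(pair[2])]]
    if (is.null(a) || is.null(b) || a == b) next
    add_bond(sys, a, b, 1)
  }
  flag_termini(sys)
  sys
}

format_pdb_name <- function(name, element) {
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 1) sprintf(" %-3s", name) else sprintf("%-4s", name)
}

#' Write a PDB file
#'
#' Emits fixed-column ATOM/HETATM records with serials renumbered 1..N
#' in traversal order, TER after each chain, CONECT records for all
#' bonds, and END. Serials above 99999 wrap with a warning.
#'
#' @param sys a `molsys`; every atom needs finite coordinates below
#'   10000 Angstrom in magnitude.
#' @param path output file path, or `NULL` to return the lines.
#' @return invisibly, the character vector of lines.
#' @export
write_pdb <- function(sys, path = NULL) {
  out <- character()
  serial <- 0L
  serial_of <- integer(n_atoms(sys))
  for (ci in seq_len(nrow(sys$chains))) {
    chain_id <- sys$chains$id[ci]
    if (!nzchar(chain_id)) chain_id <- " "
    wrote_any <- FALSE
    for (ri in which(sys$residues$chain == ci)) {
      res <- sys$residues[ri, ]
      rec <- if (res$het) "HETATM" else "ATOM  "
      for (ai in which(sys$atoms$res == ri)) {
        a <- sys$atoms[ai, ]
        xyz <- c(a$x, a$y, a$z)
        fmt <- sprintf("%8.3f", xyz)
        if (any(nchar(fmt) > 8) || any(abs(xyz) >= 10000))
          stop("unrepresentable in PDB: coordinate out of range")
        serial <- serial + 1L
        pserial <- ((serial - 1L) %% 99999L) + 1L
        if (serial > 99999L && pserial == 1L)
          warning("PDB serial overflow: wrapping at 99999")
        serial_of[ai] <- pserial
        out <- c(out, sprintf(
          "%s%5d %s%s%-3s %s%4d%s   %s%s%s%6.2f%6.2f          %2s",
          rec, pserial, format_pdb_name(a$name, a$element), " ",
          substr(res$name, 1, 3), substr(chain_id, 1, 1), res$id,
          ifelse(nzchar(res$icode), res$icode, " "),
          fmt[1], fmt[2], fmt[3], a$occupancy, a$temp_factor,
          toupper(a$element)))
        wrote_any <- TRUE
      }
    }
    if (wrote_any) out <- c(out, "TER")
  }
  if (nrow(sys$bonds)) {
    b <- sys$bonds[order(sys$bonds$i, sys$bonds$j), , drop = FALSE]
    out <- c(out, sprintf("CONECT%5d%5d", serial_of[b$i], serial_of[b$j]))
  }
  out <- c(out, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
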