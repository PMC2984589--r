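# MOL / SDF V2000 connection-table reader/writer.

#' Read a MOL/SDF (V2000) file
#'
#' Parses the counts line, atom block (`x y z symbol`), bond block
#' (`a b order`, code 4 = aromatic) and `M  CHG` formal-charge lines of
#' every record; records are separated by `$$$$`.
#'
#' @param source path, connection, or text.
#' @return a list of `molsys` objects, one per record.
#' @export
read_sdf <- function(source) {
  lines <- source_lines(source)
  recs <- split(lines, cumsum(c(0, head(trimws(lines), -1) == "$$$$")))
  out <- list()
  for (rec in recs) {
    rec <- rec[trimws(rec) != "$$$$"]
    if (!any(nzchar(trimws(rec)))) next
    out[[length(out) + 1L]] <- parse_molblock(rec)
  }
  out
}

parse_molblock <- function(lines) {
  if (length(lines) < 4) stop("truncated MOL block")
  title <- trimws(lines[1])
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("bad MOL counts line")
  mend <- which(trimws(lines) == "M  END")
  if (!length(mend)) stop("truncated MOL block")
  sys <- new_system()
  ch <- add_chain(sys, "")
  res <- add_residue(sys, ch, if (nzchar(title)) substr(title, 1, 3) else "MOL",
                     1L, het = TRUE)
  for (k in seq_len(na)) {
    line <- lines[4 + k]
    x <- suppressWarnings(as.numeric(substr(line, 1, 10)))
    y <- suppressWarnings(as.numeric(substr(line, 11, 20)))
    z <- suppressWarnings(as.numeric(substr(line, 21, 30)))
    sym <- normalize_element(trimws(substr(line, 31, 34)))
    if (anyNA(c(x, y, z))) stop(sprintf("bad MOL atom line %d", k))
    counts_el <- table(sys$atoms$element[sys$atoms$res == res])
    idx <- (counts_el[sym] %||% 0)
    idx <- if (is.na(idx)) 0 else idx
    add_atom(sys, res, paste0(sym, idx + 1), sym, c(x, y, z))
  }
  for (k in seq_len(nb)) {
    line <- lines[4 + na + k]
    i <- suppressWarnings(as.integer(substr(line, 1, 3)))
    j <- suppressWarnings(as.integer(substr(line, 4, 6)))
    o <- suppressWarnings(as.integer(substr(line, 7, 9)))
    if (anyNA(c(i, j, o))) stop(sprintf("bad MOL bond line %d", k))
    order <- if (o == 4) BOND_AROMATIC else o
    if (!order %in% c(1, 2, 3, BOND_AROMATIC))
      stop(sprintf("unsupported MOL bond order code %d", o))
    add_bond(sys, i, j, order)
  }
  for (line in lines[seq_len(mend[1])]) {
    if (startsWith(line, "M  CHG")) {
      f <- strsplit(trimws(substr(line, 7, nchar(line))), "[[:space:]]+")[[1]]
      n <- as.integer(f[1])
      for (k in seq_len(n)) {
        ai <- as.integer(f[2 * k])
        chg <- as.integer(f[2 * k + 1])
        sys$atoms$formal_charge[ai] <- chg
      }
    }
  }
  sys
}

mol_block <- function(sys, title = "MOL") {
  a <- sys$atoms
  b <- sys$bonds
  out <- c(substr(title, 1, 80), "  molkit", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(a), nrow(b)))
  out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        a$x, a$y, a$z, a$element))
  if (nrow(b)) {
    code <- ifelse(b$order == BOND_AROMATIC, 4L, as.integer(b$order))
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, code))
  }
  chg <- which(a$formal_charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      out <- c(out, paste0(sprintf("M  CHG%3d", length(grp)),
                           paste0(sprintf("%4d%4d", grp,
                                          a$formal_charge[grp]),
                                  collapse = "")))
    }
  }
  c(out, "M  END")
}

#' Write an SDF (V2000) file
#'
#' @param systems a `molsys` or list of them; one record per system,
#'   separated by `$$$$`.
#' @param path output path, or `NULL` to return the lines.
#' @return invisibly, the character vector of lines.
#' @export
write_sdf <- function(systems, path = NULL) {
  if (inherits(systems, "molsys")) systems <- list(systems)
  out <- character()
  for (sys in systems) {
    title <- if (nrow(sys$residues)) sys$residues$name[1] else "MOL"
    out <- c(out, mol_block(sys, title), "$$$$")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
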