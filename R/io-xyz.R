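# Plain XYZ reader/writer.

#' Read an XYZ file
#'
#' First line: atom count; second line: free comment; then one
#' `symbol x y z` line per atom. All atoms land in a single free
#' molecule (one residue in an unnamed chain); no bonds.
#'
#' @param source path, connection, or text.
#' @return a `molsys`.
#' @export
read_xyz <- function(source) {
  lines <- source_lines(source)
  if (!length(lines)) stop("empty XYZ input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ header is not an atom count")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) stop("XYZ atom count mismatch")
  sys <- new_system()
  ch <- add_chain(sys, "")
  res <- add_residue(sys, ch, "MOL", 1L, het = TRUE)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(body[k]), "[[:space:]]+")[[1]]
    if (length(f) < 4) stop("XYZ atom count mismatch")
    pos <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(pos)) stop(sprintf("bad XYZ coordinate on atom line %d", k))
    el <- normalize_element(f[1])
    add_atom(sys, res, el, el, pos)
  }
  sys
}

#' Write an XYZ file
#'
#' @param sys a `molsys`.
#' @param path output path, or `NULL` to return the lines.
#' @param comment second header line.
#' @return invisibly, the character vector of lines.
#' @export
write_xyz <- function(sys, path = NULL, comment = "written by molkit") {
  a <- sys$atoms
  out <- c(as.character(nrow(a)), comment,
           sprintf("%-2s %12.6f %12.6f %12.6f", a$element, a$x, a$y, a$z))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
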