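# Expression-based atom selection.
#
# Grammar (case- and whitespace-insensitive keywords):
#   expr   := term (OR term)*
#   term   := factor (AND factor)*
#   factor := NOT factor | '(' expr ')' | predicate '(' arg ')'
#           | 'backbone' | 'all'
#   predicate := element | name | residue | chain | residueID
#
# Evaluation is pure; flags are only written by apply_selection().

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "HA")

sel_tokenize <- function(text) {
  tokens <- list()
  i <- 1
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1; next }
    if (ch %in% c("(", ")")) {
      tokens[[length(tokens) + 1]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1
      next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[A-Za-z0-9_*'+-]+", substr(text, i, n)))
    if (!length(m) || !nzchar(m))
      stop(sprintf("selection syntax error at offset %d: unexpected '%s'",
                   i, ch))
    tokens[[length(tokens) + 1]] <- list(type = "word", value = m, pos = i)
    i <- i + nchar(m)
  }
  tokens
}

#' Parse a selection expression
#'
#' Supported predicates: `element(SYM)`, `name(ATOMNAME)`,
#' `residue(RESNAME)`, `chain(ID)`, `residueID(N)` or
#' `residueID(A-B)` (inclusive range), plus the bare keywords
#' `backbone` and `all`, combined with `AND`, `OR`, `NOT` and
#' parentheses.
#'
#' @param text expression text.
#' @return a `selexpr` predicate tree.
#' @export
parse_expression <- function(text) {
  tokens <- sel_tokenize(text)
  pos <- 1
  end_offset <- max(nchar(text), 1)

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tok <- tokens[[pos]]; pos <<- pos + 1; tok }
  expect <- function(type) {
    tok <- peek()
    if (is.null(tok) || tok$type != type)
      stop(sprintf("selection syntax error at offset %d: expected '%s'",
                   if (is.null(tok)) end_offset else tok$pos, type))
    advance()
  }
  is_kw <- function(tok, kw)
    !is.null(tok) && tok$type == "word" && toupper(tok$value) == kw

  parse_expr <- function() {
    node <- parse_term()
    while (is_kw(peek(), "OR")) {
      advance()
      node <- list(op = "OR", left = node, right = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (is_kw(peek(), "AND")) {
      advance()
      node <- list(op = "AND", left = node, right = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok))
      stop(sprintf("selection syntax error at offset %d: unexpected end",
                   end_offset))
    if (is_kw(tok, "NOT")) {
      advance()
      return(list(op = "NOT", arg = parse_factor()))
    }
    if (tok$type == "(") {
      advance()
      node <- parse_expr()
      expect(")")
      return(node)
    }
    if (tok$type != "word")
      stop(sprintf("selection syntax error at offset %d: unexpected '%s'",
                   tok$pos, tok$value))
    advance()
    word <- tolower(tok$value)
    if (word == "all") return(list(op = "PRED", kind = "all", arg = NULL))
    if (word == "backbone")
      return(list(op = "PRED", kind = "backbone", arg = NULL))
    valid <- c("element", "name", "residue", "chain", "residueid")
    if (!word %in% valid)
      stop(sprintf(paste0("unknown predicate '%s' at offset %d; valid ",
                          "predicates: %s, backbone, all"),
                   tok$value, tok$pos,
                   paste(c("element", "name", "residue", "chain",
                           "residueID"), collapse = ", ")))
    expect("(")
    argtok <- peek()
    if (is.null(argtok) || argtok$type != "word")
      stop(sprintf("selection syntax error at offset %d: missing argument",
                   if (is.null(argtok)) end_offset else argtok$pos))
    advance()
    expect(")")
    list(op = "PRED", kind = word, arg = argtok$value)
  }

  node <- parse_expr()
  if (!is.null(peek()))
    stop(sprintf("selection syntax error at offset %d: trailing input",
                 peek()$pos))
  structure(node, class = "selexpr")
}

## Vectorized evaluation: returns a logical per atom, flags untouched.
eval_selection <- function(sys, node) {
  a <- sys$atoms
  if (!is.null(node$op) && node$op == "AND")
    return(eval_selection(sys, node$left) & eval_selection(sys, node$right))
  if (node$op == "OR")
    return(eval_selection(sys, node$left) | eval_selection(sys, node$right))
  if (node$op == "NOT")
    return(!eval_selection(sys, node$arg))
  switch(node$kind,
    all = rep(TRUE, nrow(a)),
    element = toupper(a$element) == toupper(node$arg),
    name = toupper(a$name) == toupper(node$arg),
    residue = {
      rn <- sys$residues$name[a$res]
      toupper(rn) == toupper(node$arg)
    },
    chain = {
      cid <- sys$chains$id[sys$residues$chain[a$res]]
      toupper(cid) == toupper(node$arg)
    },
    residueid = {
      rid <- sys$residues$id[a$res]
      if (grepl("^-?[0-9]+--?[0-9]+$", node$arg)) {
        parts <- regmatches(node$arg,
                            regexec("^(-?[0-9]+)-(-?[0-9]+)$", node$arg))[[1]]
        lo <- as.integer(parts[2]); hi <- as.integer(parts[3])
        rid >= lo & rid <= hi
      } else {
        v <- suppressWarnings(as.integer(node$arg))
        if (is.na(v)) stop("residueID argument must be an integer or range")
        rid == v
      }
    },
    backbone = {
      rn <- sys$residues$name[a$res]
      het <- sys$residues$het[a$res]
      a$name %in% BACKBONE_NAMES & !het
    },
    stop("unknown predicate kind: ", node$kind)
  )
}

#' Apply a selection to a system
#'
#' Sets every atom's selection flag to the value of the expression on
#' that atom (previous flags are overwritten).
#'
#' @param sys a `molsys`.
#' @param expr a `selexpr` from [parse_expression()], or expression
#'   text.
#' @return the number of selected atoms.
#' @export
apply_selection <- function(sys, expr) {
  if (is.character(expr)) expr <- parse_expression(expr)
  mask <- eval_selection(sys, expr)
  sys$atoms$selected <- mask
  sum(mask)
}

#' Clear all selection flags
#' @param sys a `molsys`.
#' @return invisibly, the system.
#' @export
deselect <- function(sys) {
  sys$atoms$selected <- rep(FALSE, nrow(sys$atoms))
  invisible(sys)
}
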