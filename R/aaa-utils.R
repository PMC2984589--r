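# Internal numeric helpers and element data shared across the package.

#' @importFrom utils head
#' @importFrom stats dist rnorm optimize
#' @importFrom tools file_ext
NULL

DEG <- pi / 180

## Coulomb constant in kcal * Angstrom / (mol * e^2)
COULOMB_CONSTANT <- 332.0637

## Boltzmann constant in kcal/(mol*K)
KB_KCAL <- 0.0019872041

## Conversion kcal/mol/Angstrom/amu -> Angstrom/fs^2
ACC_CONV <- 4.184e-4

## Minimal periodic table: symbol, atomic number, mass (amu),
## default valence(s) used by bond-order perception / valence filling.
PERIODIC_TABLE <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I",
             "Na", "K", "Mg", "Ca", "Zn", "Fe"),
  number = c(1L, 5L, 6L, 7L, 8L, 9L, 15L, 16L, 17L, 35L, 53L,
             11L, 19L, 12L, 20L, 30L, 26L),
  mass = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 30.974,
           32.06, 35.453, 79.904, 126.904, 22.990, 39.098, 24.305,
           40.078, 65.38, 55.845),
  stringsAsFactors = FALSE
)

is_known_element <- function(sym) sym %in% PERIODIC_TABLE$symbol

#' Normalize an element symbol to canonical capitalization
#'
#' @param sym character vector of element symbols in any case.
#' @return character vector with standard capitalization ("CL" -> "Cl").
#' @keywords internal
normalize_element <- function(sym) {
  sym <- trimws(sym)
  out <- paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, nchar(sym))))
  out[sym == ""] <- ""
  out
}

element_mass <- function(sym) {
  m <- PERIODIC_TABLE$mass[match(sym, PERIODIC_TABLE$symbol)]
  if (anyNA(m)) stop("unknown element(s): ",
                     paste(unique(sym[is.na(m)]), collapse = ", "))
  m
}

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Wrap angle in degrees to (-180, 180]
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a private RNG seed, restoring the caller's
## RNG state afterwards (seeded operations never leak global state).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}
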