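#' Element property table
#'
#' Returns the table of per-element properties used throughout the package:
#' van der Waals radius, covalent radius (both in Angstrom) and atomic mass
#' (amu). Radii follow the widely used Bondi/Alvarez van der Waals values and
#' Cordero covalent radii; masses are standard atomic weights.
#'
#' @return A data.frame with columns \code{symbol}, \code{vdw}, \code{covalent}
#'   and \code{mass}, one row per supported element.
#' @examples
#' element_table()
#' @export
element_table <- function() {
  data.frame(
    symbol   = c("H",    "C",    "N",    "O",    "F",    "Cl",   "Br"),
    vdw      = c(1.20,   1.70,   1.55,   1.52,   1.47,   1.75,   1.85),
    covalent = c(0.31,   0.76,   0.71,   0.66,   0.57,   1.02,   1.20),
    mass     = c(1.008,  12.011, 14.007, 15.999, 18.998, 35.45,  79.904),
    stringsAsFactors = FALSE
  )
}

# look up one column of the element table for a vector of symbols;
# errors on unsupported symbols, naming the offenders
element_property <- function(symbols, what = c("mass", "vdw", "covalent")) {
  what <- match.arg(what)
  tab <- element_table()
  idx <- match(symbols, tab$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "))
  }
  tab[[what]][idx]
}

# case-normalize element symbols ("CL" -> "Cl", "h" -> "H")
normalize_symbol <- function(symbols) {
  s <- tolower(symbols)
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}
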