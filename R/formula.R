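#' Parse a chemical formula string
#'
#' Parses an empirical formula such as `"C6H12O6"` into a named integer
#' vector of element counts.  Element symbols follow the usual one-capital
#' (+ optional lowercase) convention; the pseudo-elements `"R"` and `"X"`
#' used for lumped species (acyl chains, generic residues) are ordinary
#' symbols and participate in balance arithmetic like any other element.
#' An omitted count reads as 1.  The empty string parses to an empty
#' (zero-element) formula.
#'
#' @param text a single formula string.
#' @return named integer vector, element symbol -> count, in Hill order
#'   (see [format_formula()]).
#' @seealso [format_formula()], [molar_mass()]
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (length(text) != 1L || !is.character(text) || is.na(text)) {
    stop("formula must be a single character string")
  }
  if (text == "") {
    return(stats::setNames(integer(0), character(0)))
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  matched <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(matched)) != nchar(text)) {
    # find the first position not covered by a token
    covered <- rep(FALSE, nchar(text))
    if (tokens[1] != -1) {
      for (i in seq_along(tokens)) {
        covered[seq(tokens[i], length.out = attr(tokens, "match.length")[i])] <- TRUE
      }
    }
    bad <- which(!covered)[1]
    stop(sprintf("malformed formula '%s': unexpected token at position %d ('%s')",
                 text, bad, substr(text, bad, bad)))
  }
  syms <- sub("[0-9]+$", "", matched)
  cnts <- sub("^[A-Z][a-z]?", "", matched)
  cnts <- ifelse(cnts == "", "1", cnts)
  counts <- suppressWarnings(as.integer(cnts))
  if (anyNA(counts)) {
    stop(sprintf("malformed formula '%s': non-integer count in '%s'",
                 text, matched[which(is.na(counts))[1]]))
  }
  out <- tapply(counts, syms, sum)
  out <- stats::setNames(as.integer(out), names(out))
  out <- out[out != 0L]
  out[hill_order(names(out))]
}

# Hill order: C first, H second (when C present), then alphabetical.
# Without C, strictly alphabetical (standard Hill convention).
hill_order <- function(syms) {
  if (length(syms) == 0L) return(integer(0))
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms)
  }
  match(ord, syms)
}

#' Serialize an element-count map to a canonical Hill-order string
#'
#' @param counts named numeric/integer vector of element counts.
#' @return a single string; counts of 1 are omitted, empty input gives `""`.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0L) return("")
  counts <- counts[hill_order(names(counts))]
  paste0(names(counts), ifelse(counts == 1, "", as.character(counts)),
         collapse = "")
}

# Standard atomic masses (g/mol); pseudo-elements R and X are massless so
# that lumped species can still be audited for balance without inventing
# a mass for an unspecified residue.
.ATOMIC_MASS <- c(
  C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974, S = 32.06,
  Na = 22.990, K = 39.098, Mg = 24.305, Ca = 40.078, Fe = 55.845,
  Zn = 65.38, Cl = 35.45, Mn = 54.938, Cu = 63.546, Co = 58.933,
  Mo = 95.95, Se = 78.971, I = 126.904, B = 10.81, R = 0, X = 0
)

#' Molar mass of a formula
#'
#' @param formula either a formula string or a named element-count vector.
#' @return molar mass in g/mol.  Pseudo-elements R/X contribute zero mass.
#' @export
molar_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0L) return(0)
  unknown <- setdiff(names(formula), names(.ATOMIC_MASS))
  if (length(unknown) > 0L) {
    stop("no atomic mass for element(s): ", paste(unknown, collapse = ", "))
  }
  sum(.ATOMIC_MASS[names(formula)] * as.numeric(formula))
}

# Sum scaled formulas: list of count vectors, numeric coefficients.
# Returns the net element map (may be negative); used by the balance audit.
combine_formulas <- function(formulas, coefficients) {
  acc <- numeric(0)
  for (i in seq_along(formulas)) {
    f <- formulas[[i]]
    if (length(f) == 0L) next
    for (el in names(f)) {
      acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0) +
        coefficients[i] * f[[el]]
    }
  }
  acc[abs(acc) > 0]
}
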