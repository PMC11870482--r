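## Monoisotopic element masses (Da). C is exactly 12 by definition.
.MONOISOTOPIC <- c(C = 12.0, H = 1.00782503, N = 14.00307401, O = 15.99491462)
.PROTON <- 1.00727646

#' Monoisotopic mass constants
#'
#' Element table and derived constants used throughout the mass module:
#' monoisotopic masses of C, H, N, O; the proton mass; water (H2O); the
#' acetyl-group difference (C2H2O, 42.0105646 Da, the mass lost on
#' N-deacetylation of an amino sugar); and H2 (2.0156501 Da, gained on
#' borohydride reduction of the reducing end).
#'
#' @return Named list with `elements`, `proton`, `water`, `acetyl_delta`,
#'   `h2`.
#' @export
mass_constants <- function() {
  list(
    elements = .MONOISOTOPIC,
    proton = .PROTON,
    water = monoisotopic_mass(c(H = 2, O = 1)),
    acetyl_delta = monoisotopic_mass(c(C = 2, H = 2, O = 1)),
    h2 = monoisotopic_mass(c(H = 2))
  )
}

#' Parse or normalise an elemental formula
#'
#' Accepts either a named numeric vector of element counts (e.g.
#' `c(C = 19, H = 30, N = 2, O = 12)`) or a Hill-style string such as
#' `"C19H30N2O12"`. Counts must be non-negative integers over the supported
#' elements C, H, N, O.
#'
#' @param x Formula as named vector or string.
#' @return Named integer vector over `c("C","H","N","O")`.
#' @export
as_formula <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    if (!nzchar(x)) return(setNames(integer(4L), names(.MONOISOTOPIC)))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1L]]
    toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1L]]
    if (!length(toks) || paste(toks, collapse = "") != x)
      stop("cannot parse formula string: ", x)
    el <- sub("[0-9]*$", "", toks)
    n <- sub("^[A-Z][a-z]?", "", toks)
    n <- ifelse(nzchar(n), as.integer(n), 1L)
    x <- tapply(n, el, sum)
  }
  unknown <- setdiff(names(x), names(.MONOISOTOPIC))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  out <- setNames(integer(length(.MONOISOTOPIC)), names(.MONOISOTOPIC))
  out[names(x)] <- as.integer(round(as.numeric(x)))
  if (any(out < 0L)) stop("element counts must be non-negative")
  out
}

#' @rdname as_formula
#' @param f A formula (any form accepted by [as_formula()]).
#' @return `format_formula()`: the Hill-style string (C, H, then N, O;
#'   elements with zero count omitted).
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  f <- f[f > 0L]
  if (!length(f)) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' Formula arithmetic
#'
#' Element-wise addition and subtraction of elemental formulas. Subtraction
#' that would make any count negative is an error (chemically impossible
#' composition).
#'
#' @param a,b Formulas (any form accepted by [as_formula()]).
#' @return Named integer vector.
#' @export
formula_add <- function(a, b) as_formula(as_formula(a) + as_formula(b))

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  out <- as_formula(a) - as_formula(b)
  if (any(out < 0L))
    stop("formula subtraction would give a negative element count (",
         format_formula(as_formula(a)), " - ", format_formula(as_formula(b)), ")")
  out
}

#' Free-monosaccharide formulas of peptidoglycan glycan units
#'
#' The six sugar units occurring in peptidoglycan glycan fragments, as free
#' monosaccharides: GlcNAc (C8H15NO6), its deacetylated form GlcN
#' (C6H13NO5), MurNAc (C11H19NO8), 1,6-anhydro-MurNAc (C11H17NO7; the
#' signature product of lytic transglycosylases such as MltA), and the
#' deacetylated MurN (C9H17NO7) and 1,6-anhydro-MurN (C9H15NO6). Each
#' deacetylated unit is exactly its parent minus C2H2O.
#'
#' @return Named list of elemental formulas.
#' @export
glycan_units <- function() {
  list(
    GlcNAc    = as_formula(c(C = 8,  H = 15, N = 1, O = 6)),
    GlcN      = as_formula(c(C = 6,  H = 13, N = 1, O = 5)),
    MurNAc    = as_formula(c(C = 11, H = 19, N = 1, O = 8)),
    anhMurNAc = as_formula(c(C = 11, H = 17, N = 1, O = 7)),
    MurN      = as_formula(c(C = 9,  H = 17, N = 1, O = 7)),
    anhMurN   = as_formula(c(C = 9,  H = 15, N = 1, O = 6))
  )
}

.ANHYDRO_UNITS <- c("anhMurNAc", "anhMurN")

#' Define a peptidoglycan glycan fragment
#'
#' A glycan fragment is an ordered chain of sugar units (non-reducing to
#' reducing end), optionally borohydride-reduced at the reducing end.
#' 1,6-anhydro units carry an internal ring instead of a free aldehyde, so
#' an anhydro unit at the reducing end cannot be reduced.
#'
#' @param units Character vector of unit names (see [glycan_units()]),
#'   non-reducing end first.
#' @param reduced Logical; reducing end reduced with sodium borohydride
#'   (+H2)?
#' @param name Optional display name; defaults to the units joined by `-`.
#' @return An object of class `glycan_fragment`.
#' @examples
#' glycan_fragment(c("GlcNAc", "anhMurNAc"))  # GlcNAc-MurNAcAnh
#' @export
glycan_fragment <- function(units, reduced = FALSE, name = NULL) {
  units <- as.character(units)
  if (!length(units)) stop("a glycan fragment needs at least one unit")
  bad <- setdiff(units, names(glycan_units()))
  if (length(bad)) stop("unknown glycan unit(s): ", paste(bad, collapse = ", "))
  if (isTRUE(reduced) && units[length(units)] %in% .ANHYDRO_UNITS)
    stop("a 1,6-anhydro reducing end has no aldehyde and cannot be reduced")
  structure(list(
    units = units,
    reduced = isTRUE(reduced),
    name = if (is.null(name)) paste(units, collapse = "-") else name
  ), class = "glycan_fragment")
}

#' @export
print.glycan_fragment <- function(x, ...) {
  cat("<glycan_fragment> ", x$name,
      if (x$reduced) " (reduced)" else "", "\n", sep = "")
  f <- fragment_formula(x)
  cat("  ", format_formula(f), "  ",
      sprintf("%.4f Da, [M+H]+ %.4f", monoisotopic_mass(f),
              mz_value(monoisotopic_mass(f), 1L)), "\n", sep = "")
  invisible(x)
}

#' Elemental formula of a glycan fragment
#'
#' Sum of the free-unit formulas minus one H2O per glycosidic bond
#' (condensation), plus H2 when the fragment is borohydride-reduced.
#'
#' @param fragment A [glycan_fragment()], or a character vector of unit
#'   names (taken as an unreduced fragment).
#' @return Named integer vector of element counts.
#' @export
fragment_formula <- function(fragment) {
  if (is.character(fragment)) fragment <- glycan_fragment(fragment)
  stopifnot(inherits(fragment, "glycan_fragment"))
  units <- glycan_units()
  f <- Reduce(`+`, units[fragment$units])
  k <- length(fragment$units)
  f <- f - (k - 1L) * as_formula(c(H = 2, O = 1))
  if (fragment$reduced) f <- f + as_formula(c(H = 2))
  as_formula(f)
}

#' Monoisotopic mass of a formula or fragment
#'
#' @param x An elemental formula (named vector or string) or a
#'   [glycan_fragment()].
#' @return Neutral monoisotopic mass in Da (0 for an empty formula).
#' @export
monoisotopic_mass <- function(x) {
  if (inherits(x, "glycan_fragment")) x <- fragment_formula(x)
  f <- as_formula(x)
  sum(f * .MONOISOTOPIC[names(f)])
}

#' m/z of a protonated ion
#'
#' Positive-mode `[M + zH]z+` mass-to-charge: `(M + z * m_proton) / z`.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param z Charge state, integer >= 1 (default 1; the small glycan
#'   fragments handled here are singly charged in practice).
#' @return m/z in Th.
#' @export
mz_value <- function(neutral_mass, z = 1L) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1L)) stop("charge `z` must be an integer >= 1")
  (neutral_mass + z * .PROTON) / z
}
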