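#' Parse a chemical formula string
#'
#' Converts a Hill-style formula such as `"C5H8NO4"` into a named
#' `chem_formula` object (a named integer vector of atom counts). An element
#' symbol without a trailing number has an implicit count of one. Elements
#' repeated in the string are summed.
#'
#' Formulas here describe the complete derivatized fragment ion, including
#' atoms added by MOX/TBDMS derivatization (C, H, N, O, Si), not just the
#' metabolite backbone.
#'
#' @param text A formula string, e.g. `"C17H36NO4Si2"`.
#' @return A `chem_formula` object: named integer vector of atom counts.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("CO2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula: '", text, "'", call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Z][a-z]?", "", tokens)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  bad <- setdiff(sym, known_elements())
  if (length(bad) > 0L) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(cnt <= 0L)) stop("atom counts must be positive", call. = FALSE)
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out, class = "chem_formula")
}

#' Render a chemical formula back to a string
#'
#' Inverse of [parse_formula()]: `parse_formula(format_formula(f))` equals `f`.
#'
#' @param f A `chem_formula` object or named integer vector.
#' @return A single formula string.
#' @export
format_formula <- function(f) {
  f <- as_chem_formula(f)
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' Coerce to a chem_formula
#'
#' @param x A `chem_formula`, a named numeric vector of atom counts, or a
#'   formula string.
#' @return A `chem_formula` object.
#' @export
as_chem_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) {
    if (any(x < 0) || any(x != round(x))) {
      stop("atom counts must be non-negative integers", call. = FALSE)
    }
    x <- x[x > 0]
    if (length(x) == 0L) stop("formula must contain at least one atom", call. = FALSE)
    out <- as.integer(x)
    names(out) <- names(x)
    return(structure(out, class = "chem_formula"))
  }
  stop("cannot coerce to chem_formula", call. = FALSE)
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Number of atoms of one element in a formula
#'
#' @param f A `chem_formula` (or coercible).
#' @param element Element symbol, e.g. `"C"`.
#' @return Integer count (0 if the element is absent).
#' @export
element_count <- function(f, element) {
  f <- as_chem_formula(f)
  if (element %in% names(f)) unname(f[[element]]) else 0L
}

# element symbols the default abundance table knows about
known_elements <- function() c("C", "H", "N", "O", "Si", "S", "P")
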