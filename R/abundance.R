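#' Default natural isotope abundance table
#'
#' Returns the package's built-in table of natural isotope abundances,
#' expressed per element as fractional abundances indexed by integer mass
#' shift (0 = lightest isotope). Values follow the IUPAC representative
#' isotopic compositions. The table covers the elements that occur in
#' MOX/TBDMS-derivatized metabolite fragments: C, H, N, O, Si, S (plus P).
#'
#' Mass shifts are consecutive from 0; isotopes that do not exist at a given
#' shift (e.g. sulfur at +3) carry abundance 0 so every element's vector is
#' a dense distribution over shifts.
#'
#' @return An `isotope_table` object: a named list with one numeric
#'   abundance vector per element plus `source` and `version` attributes.
#' @examples
#' tab <- default_isotope_table()
#' tab$C   # 12C, 13C
#' @export
default_isotope_table <- function() {
  isotope_table(
    list(
      C  = c(0.9893, 0.0107),
      H  = c(0.999885, 0.000115),
      N  = c(0.99636, 0.00364),
      O  = c(0.99757, 0.00038, 0.00205),
      Si = c(0.92223, 0.04685, 0.03092),
      S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
      P  = c(1)
    ),
    source = "IUPAC representative isotopic compositions",
    version = "2013"
  )
}

#' Construct an isotope abundance table
#'
#' @param abundances Named list; one numeric vector per element giving
#'   fractional abundances at mass shifts 0, 1, 2, ... Each vector must be
#'   non-negative and sum to 1 (tolerance 1e-9 after normalization check).
#' @param source Character label describing where the values come from.
#' @param version Character version label.
#' @return An `isotope_table` object.
#' @export
isotope_table <- function(abundances, source = "user", version = "0") {
  if (!is.list(abundances) || is.null(names(abundances)) ||
      any(!nzchar(names(abundances)))) {
    stop("abundances must be a named list of numeric vectors", call. = FALSE)
  }
  for (el in names(abundances)) {
    a <- abundances[[el]]
    if (!is.numeric(a) || length(a) < 1L || any(a < 0) || any(!is.finite(a))) {
      stop("abundances for element ", el, " must be non-negative finite numbers",
           call. = FALSE)
    }
    if (abs(sum(a) - 1) > 1e-9) {
      stop("abundances for element ", el, " must sum to 1 (got ", sum(a), ")",
           call. = FALSE)
    }
  }
  structure(abundances, class = "isotope_table",
            source = source, version = version)
}

#' Read an isotope abundance table from a key-value text file
#'
#' The file is YAML: top-level keys `source` and `version` (optional) and an
#' `elements` mapping from element symbol to a list of abundances ordered by
#' mass shift starting at 0.
#'
#' @param path Path to a YAML abundance file.
#' @return An `isotope_table` object.
#' @export
read_isotope_table <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$elements)) {
    stop("abundance file must contain an 'elements' mapping", call. = FALSE)
  }
  isotope_table(lapply(raw$elements, as.numeric),
                source = raw$source %||% "file",
                version = as.character(raw$version %||% "0"))
}

#' @export
print.isotope_table <- function(x, ...) {
  cat("<isotope_table> ", length(x), " elements (",
      attr(x, "source"), ", v", attr(x, "version"), ")\n", sep = "")
  invisible(x)
}

element_abundance <- function(table, element) {
  if (!element %in% names(table)) {
    stop("element ", element, " missing from isotope abundance table",
         call. = FALSE)
  }
  table[[element]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
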