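#' Define a measured metabolite fragment
#'
#' A fragment definition ties a metabolite to the elemental composition of
#' the derivatized fragment ion actually integrated on the GC-MS, the number
#' of backbone carbons that can carry tracer 13C, and the width of the
#' measured mass-shift window.
#'
#' @param metabolite Metabolite name (e.g. `"glutamate"`).
#' @param formula Fragment ion formula (string or `chem_formula`), including
#'   derivatization atoms.
#' @param n_backbone_carbons Number of carbons in the fragment that can be
#'   tracer-labeled (metabolite backbone carbons retained in the ion).
#' @param n_measured_shifts Number of mass shifts measured beyond m+0.
#'   Defaults to `n_backbone_carbons + 2`, wide enough to capture the Si/S
#'   natural-abundance tail of TBDMS fragments.
#' @param fragment_name Label for the fragment (defaults to the nominal
#'   formula string).
#' @return A `fragment_def` object (a list).
#' @export
fragment_def <- function(metabolite, formula, n_backbone_carbons,
                         n_measured_shifts = n_backbone_carbons + 2L,
                         fragment_name = NULL) {
  formula <- as_chem_formula(formula)
  n_backbone_carbons <- as.integer(n_backbone_carbons)
  n_measured_shifts <- as.integer(n_measured_shifts)
  if (n_backbone_carbons < 0L) {
    stop("n_backbone_carbons must be non-negative", call. = FALSE)
  }
  if (n_backbone_carbons > element_count(formula, "C")) {
    stop("fragment ", metabolite, ": n_backbone_carbons (", n_backbone_carbons,
         ") exceeds the fragment's carbon count (",
         element_count(formula, "C"), ")", call. = FALSE)
  }
  if (n_measured_shifts < n_backbone_carbons) {
    stop("n_measured_shifts must be at least n_backbone_carbons", call. = FALSE)
  }
  structure(
    list(metabolite = metabolite,
         fragment_name = fragment_name %||% format_formula(formula),
         formula = formula,
         n_backbone_carbons = n_backbone_carbons,
         n_measured_shifts = n_measured_shifts),
    class = "fragment_def"
  )
}

#' @export
print.fragment_def <- function(x, ...) {
  cat("<fragment_def> ", x$metabolite, " [", x$fragment_name, "] ",
      format_formula(x$formula), ", ", x$n_backbone_carbons,
      " backbone C, window m+0..m+", x$n_measured_shifts, "\n", sep = "")
  invisible(x)
}

#' Default MOX/TBDMS fragment library
#'
#' A built-in table of derivatized fragment ion compositions for the
#' metabolites tracked in [U-13C5]glutamine tracing of the TCA cycle:
#' glutamine, glutamate, alpha-ketoglutarate, fumarate, malate, aspartate
#' and citrate. Compositions correspond to the commonly integrated
#' [M-57]+ (loss of tert-butyl) TBDMS fragments (with methoximation for
#' alpha-ketoglutarate), as tabulated in standard GC-MS derivatization
#' references. The library is a configurable default, not a claim about any
#' particular instrument method: override it with [read_fragment_library()].
#'
#' @return Named list of `fragment_def` objects keyed by metabolite.
#' @examples
#' default_fragment_library()[["glutamate"]]
#' @export
default_fragment_library <- function() {
  defs <- list(
    fragment_def("glutamine",       "C19H43N2O3Si3", 5, fragment_name = "m431"),
    fragment_def("glutamate",       "C19H42NO4Si3",  5, fragment_name = "m432"),
    fragment_def("alpha-ketoglutarate", "C14H28NO5Si2", 5, fragment_name = "m346"),
    fragment_def("fumarate",        "C12H23O4Si2",   4, fragment_name = "m287"),
    fragment_def("malate",          "C18H39O5Si3",   4, fragment_name = "m419"),
    fragment_def("aspartate",       "C18H40NO4Si3",  4, fragment_name = "m418"),
    fragment_def("citrate",         "C20H39O6Si3",   6, fragment_name = "m459")
  )
  stats::setNames(defs, vapply(defs, `[[`, "", "metabolite"))
}

#' Read a fragment library from a TSV file
#'
#' Expected columns: `metabolite`, `fragment_name`, `formula`,
#' `n_backbone_carbons` and optionally `n_measured_shifts` (defaulting to
#' `n_backbone_carbons + 2`).
#'
#' @param path Path to a tab-separated fragment definition file.
#' @return Named list of `fragment_def` objects keyed by metabolite.
#' @export
read_fragment_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("metabolite", "fragment_name", "formula", "n_backbone_carbons")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("fragment library is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$metabolite)) {
    stop("fragment library has duplicated metabolite entries", call. = FALSE)
  }
  defs <- lapply(seq_len(nrow(df)), function(i) {
    nms <- if ("n_measured_shifts" %in% names(df) &&
               !is.na(df$n_measured_shifts[i])) {
      as.integer(df$n_measured_shifts[i])
    } else {
      as.integer(df$n_backbone_carbons[i]) + 2L
    }
    fragment_def(df$metabolite[i], df$formula[i],
                 df$n_backbone_carbons[i], nms,
                 fragment_name = df$fragment_name[i])
  })
  stats::setNames(defs, df$metabolite)
}

#' Write a fragment library to a TSV file
#'
#' @param library Named list of `fragment_def` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_library <- function(library, path) {
  df <- data.frame(
    metabolite = vapply(library, `[[`, "", "metabolite"),
    fragment_name = vapply(library, `[[`, "", "fragment_name"),
    formula = vapply(library, function(f) format_formula(f$formula), ""),
    n_backbone_carbons = vapply(library, `[[`, 0L, "n_backbone_carbons"),
    n_measured_shifts = vapply(library, `[[`, 0L, "n_measured_shifts")
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
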