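#' Reference cystine concentrations: plasma versus culture media
#'
#' Adult plasma cystine sits at roughly 20-50 uM, whereas standard culture
#' media (RPMI, DMEM) contain about 200 uM — the physiological gap that
#' makes cultured cells over-reliant on glutamine anaplerosis. These
#' reference bounds feed [cystine_fold_difference()].
#'
#' @return List with `plasma_range_uM` (length-2 numeric) and
#'   `culture_uM` (single numeric).
#' @export
cystine_reference <- function() {
  list(plasma_range_uM = c(20, 50), culture_uM = 200)
}

#' Fold difference between culture-media and plasma cystine
#'
#' Computes the range of fold differences between a culture-media
#' concentration and a physiological concentration range:
#' `culture / upper` to `culture / lower`. With the default reference
#' values this is 4- to 10-fold.
#'
#' @param reference List as returned by [cystine_reference()].
#' @return Named numeric vector with elements `min_fold` and `max_fold`.
#' @examples
#' cystine_fold_difference()  # min 4, max 10
#' @export
cystine_fold_difference <- function(reference = cystine_reference()) {
  lo <- min(reference$plasma_range_uM)
  hi <- max(reference$plasma_range_uM)
  if (lo <= 0) stop("plasma concentrations must be positive", call. = FALSE)
  c(min_fold = reference$culture_uM / hi,
    max_fold = reference$culture_uM / lo)
}

#' Reference serum amino-acid concentrations
#'
#' Mean adult-bovine-serum concentrations (uM) of the metabolites used by
#' the package's serum presets, as measured by GC-MS isotope dilution.
#'
#' @return Named numeric vector of concentrations in uM.
#' @export
serum_reference_concentrations <- function() {
  c(glutamine = 183, glutamate = 192, cystine = 0.3)
}
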