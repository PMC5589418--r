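#' Construct a mass-isotopomer distribution (MID)
#'
#' A MID is the vector of fractional abundances of a metabolite fragment's
#' isotopologues m+0, m+1, ..., m+n. Fractions must be non-negative and sum
#' to 1; index 1 of the vector is m+0 (0-based mass-shift convention
#' throughout the package).
#'
#' @param fractions Numeric vector of fractional abundances over m+0..m+n.
#' @param metabolite Optional metabolite name.
#' @param fragment Optional fragment name.
#' @param tol Tolerance on the sum-to-one check.
#' @return A `mid` object.
#' @examples
#' mid(c(0.67, 0, 0, 0, 0, 0.33), metabolite = "glutamine")
#' @export
mid <- function(fractions, metabolite = NA_character_, fragment = NA_character_,
                tol = 1e-6) {
  if (!is.numeric(fractions) || length(fractions) < 1L) {
    stop("fractions must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    stop("MID fractions must be finite and non-negative", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > tol) {
    stop("MID fractions must sum to 1 (got ", format(sum(fractions)), ")",
         call. = FALSE)
  }
  structure(as.numeric(fractions), class = "mid",
            metabolite = metabolite, fragment = fragment)
}

#' @export
print.mid <- function(x, ...) {
  lab <- attr(x, "metabolite")
  cat("<mid>", if (!is.na(lab)) paste0(" ", lab) else "", " m+0..m+",
      length(x) - 1L, "\n", sep = "")
  v <- as.numeric(x)
  names(v) <- paste0("m+", seq_along(v) - 1L)
  print(round(v, 5))
  invisible(x)
}

#' Number of mass shifts covered by a MID
#'
#' @param x A `mid` object.
#' @return Integer n such that the MID spans m+0..m+n.
#' @export
n_shifts <- function(x) length(x) - 1L

#' Discrete convolution of two non-negative vectors
#'
#' Building block for theoretical isotopologue envelopes: the distribution
#' of a sum of independent mass shifts is the convolution of the individual
#' distributions. Output length is `length(a) + length(b) - 1`; the output
#' sum equals the product of the input sums.
#'
#' @param a,b Non-negative numeric vectors (index 1 = shift 0).
#' @return Numeric vector, the linear convolution of `a` and `b`.
#' @examples
#' convolve_shifts(c(0.5, 0.5), c(0.5, 0.5))  # 0.25 0.50 0.25
#' @export
convolve_shifts <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("cannot convolve empty vectors", call. = FALSE)
  }
  if (any(a < 0) || any(b < 0)) {
    stop("convolution inputs must be non-negative", call. = FALSE)
  }
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Theoretical natural-abundance isotopologue distribution of a formula
#'
#' Computes the mass-shift distribution of a chemical formula under natural
#' isotope abundances by convolving the per-atom isotope distributions of
#' every atom in the formula, then truncating to shifts m+0..m+`n_shifts`.
#' This is the forward model that natural-abundance correction inverts.
#'
#' The returned vector is the raw truncated envelope (it sums to at most 1;
#' the mass beyond `n_shifts` is simply cut off, not renormalized), so that
#' correction-matrix columns represent true detection probabilities within
#' the measured window.
#'
#' @param formula A `chem_formula`, formula string, or named count vector.
#' @param table An `isotope_table`; defaults to [default_isotope_table()].
#' @param n_shifts Largest mass shift to retain (window is m+0..m+n_shifts).
#' @return Numeric vector of length `n_shifts + 1`.
#' @examples
#' natural_distribution("C1", n_shifts = 1)   # c(0.9893, 0.0107)
#' @export
natural_distribution <- function(formula, table = default_isotope_table(),
                                 n_shifts) {
  formula <- as_chem_formula(formula)
  if (!is.numeric(n_shifts) || length(n_shifts) != 1L || n_shifts < 0) {
    stop("n_shifts must be a single non-negative integer", call. = FALSE)
  }
  n_shifts <- as.integer(n_shifts)
  dist <- 1
  for (el in names(formula)) {
    a <- element_abundance(table, el)
    # power by repeated convolution, truncating as we go to keep it cheap
    for (k in seq_len(formula[[el]])) {
      dist <- convolve_shifts(dist, a)
      if (length(dist) > n_shifts + 1L) dist <- dist[seq_len(n_shifts + 1L)]
    }
  }
  c(dist, numeric(max(0L, n_shifts + 1L - length(dist))))
}
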