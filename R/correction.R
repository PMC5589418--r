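#' Build a natural-abundance correction matrix for a fragment
#'
#' Column j (j = 0..n_backbone_carbons) of the correction matrix is the
#' theoretical mass-shift envelope of the fragment when j of its backbone
#' carbons are tracer 13C: those j carbons are removed from the natural
#' carbon pool, the remaining atoms contribute their natural-abundance
#' envelope, and the whole envelope is shifted up by j mass units. The
#' matrix maps a tracer-only mass-isotopomer distribution x to the raw
#' envelope M x that the instrument observes within the measured window.
#'
#' When a tracer `purity` below 1 is supplied, each nominally 13C tracer
#' carbon carries the 12C fraction `1 - purity`, so column j becomes a
#' binomial mixture of the pure columns. This folds tracer isotopic
#' impurity into the forward model.
#'
#' @param fragment A `fragment_def`.
#' @param table An `isotope_table`; defaults to [default_isotope_table()].
#' @param purity Isotopic purity of the tracer carbon (fraction 13C at each
#'   labeled position), default 1.
#' @return A `correction_matrix` object: numeric matrix with
#'   `n_measured_shifts + 1` rows and `n_backbone_carbons + 1` columns, with
#'   the fragment attached as attribute `fragment`.
#' @examples
#' frag <- fragment_def("x", "C1", 1, n_measured_shifts = 1)
#' build_correction_matrix(frag)
#' @export
build_correction_matrix <- function(fragment, table = default_isotope_table(),
                                    purity = 1) {
  stopifnot(inherits(fragment, "fragment_def"))
  if (!is.numeric(purity) || length(purity) != 1L || purity <= 0 || purity > 1) {
    stop("purity must be a single value in (0, 1]", call. = FALSE)
  }
  nb <- fragment$n_backbone_carbons
  nr <- fragment$n_measured_shifts + 1L
  m <- matrix(0, nrow = nr, ncol = nb + 1L)
  for (j in 0:nb) {
    # envelope of the fragment with j carbons excluded from the natural pool
    f <- unclass(fragment$formula)
    f[["C"]] <- f[["C"]] - j
    f <- f[f > 0]
    env <- if (length(f) > 0L) {
      natural_distribution(as_chem_formula(f), table,
                           n_shifts = fragment$n_measured_shifts)
    } else {
      c(1, numeric(fragment$n_measured_shifts))
    }
    # each nominal tracer carbon is 13C (shift +1) w.p. purity, else 12C
    w <- stats::dbinom(0:j, size = j, prob = purity)
    for (k in 0:j) {
      if (w[k + 1L] == 0) next
      rows <- (k + 1L):nr
      m[rows, j + 1L] <- m[rows, j + 1L] +
        w[k + 1L] * env[seq_len(nr - k)]
    }
  }
  structure(m, class = c("correction_matrix", "matrix"),
            fragment = fragment, purity = purity)
}

#' Correct a raw mass-isotopomer measurement for natural abundance
#'
#' Solves `matrix %*% x ~ raw` for the tracer-only mass-isotopomer
#' distribution x by non-negative least squares, then renormalizes x to sum
#' to 1. With noiseless input generated by the forward model the true
#' distribution is recovered to numerical precision; with noisy input the
#' non-negativity constraint prevents the small negative fractions that
#' plague unconstrained inversion.
#'
#' @param raw Numeric vector of raw intensities over m+0..m+n (arbitrary
#'   scale); length must equal `nrow(matrix)`.
#' @param matrix A `correction_matrix` from [build_correction_matrix()].
#' @return A `mid` over m+0..m+n_backbone_carbons, labeled with the
#'   fragment's metabolite.
#' @examples
#' frag <- fragment_def("x", "C1", 1, n_measured_shifts = 1)
#' M <- build_correction_matrix(frag)
#' correct_mid(as.numeric(M %*% c(0.5, 0.5)), M)
#' @export
correct_mid <- function(raw, matrix) {
  stopifnot(inherits(matrix, "correction_matrix"))
  raw <- as.numeric(raw)
  if (any(!is.finite(raw))) stop("raw intensities must be finite", call. = FALSE)
  if (length(raw) != nrow(matrix)) {
    stop("raw vector length (", length(raw), ") does not match matrix rows (",
         nrow(matrix), ")", call. = FALSE)
  }
  if (all(raw == 0)) {
    stop("all-zero raw intensity vector cannot be corrected", call. = FALSE)
  }
  if (any(raw < 0)) {
    stop("raw intensities must be non-negative", call. = FALSE)
  }
  M <- unclass(matrix)
  attributes(M) <- attributes(M)["dim"]
  # scale-invariant solve: normalize intensities first for conditioning
  x <- pracma::lsqnonneg(M, raw / sum(raw))$x
  if (sum(x) <= 0) {
    stop("correction produced an all-zero solution; raw data inconsistent ",
         "with the fragment's envelope", call. = FALSE)
  }
  frag <- attr(matrix, "fragment")
  mid(x / sum(x), metabolite = frag$metabolite, fragment = frag$fragment_name)
}

#' Correct a long-format raw MID table
#'
#' Applies [correct_mid()] to every (sample, metabolite, fragment) group of
#' a long-format raw intensity table, using per-metabolite correction
#' matrices built from a fragment library.
#'
#' @param raw_table Data frame with columns `sample_id`, `condition`,
#'   `metabolite`, `fragment_name`, `mass_shift`, `value` (raw intensity),
#'   as produced by [read_mid_table()] or [simulate_labeling()].
#' @param fragments Named list of `fragment_def` objects keyed by
#'   metabolite; defaults to [default_fragment_library()].
#' @param table Isotope abundance table.
#' @param purity Tracer isotopic purity passed to
#'   [build_correction_matrix()].
#' @return Data frame in the same long format, where `value` now holds the
#'   corrected tracer-only MID fractions over m+0..m+n_backbone_carbons.
#' @export
correct_mid_table <- function(raw_table, fragments = default_fragment_library(),
                              table = default_isotope_table(), purity = 1) {
  validate_mid_table(raw_table)
  mets <- unique(raw_table$metabolite)
  missing <- setdiff(mets, names(fragments))
  if (length(missing) > 0L) {
    stop("no fragment definition for metabolite(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mats <- lapply(fragments[mets], build_correction_matrix,
                 table = table, purity = purity)
  key <- interaction(raw_table$sample_id, raw_table$metabolite,
                     raw_table$fragment_name, drop = TRUE)
  pieces <- lapply(split(raw_table, key), function(g) {
    g <- g[order(g$mass_shift), , drop = FALSE]
    corrected <- correct_mid(g$value, mats[[g$metabolite[1]]])
    data.frame(sample_id = g$sample_id[1], condition = g$condition[1],
               metabolite = g$metabolite[1],
               fragment_name = g$fragment_name[1],
               mass_shift = seq_along(corrected) - 1L,
               value = as.numeric(corrected))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
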