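#' Define an internal-standard mix for isotope-dilution quantification
#'
#' @param concentrations Named numeric vector: labeled-standard
#'   concentration in the mix (uM) per analyte, all positive.
#' @param label Mix label.
#' @return An `is_mix` object.
#' @export
internal_standard_mix <- function(concentrations, label = "IS mix") {
  if (!is.numeric(concentrations) || is.null(names(concentrations)) ||
      any(!nzchar(names(concentrations)))) {
    stop("concentrations must be a named numeric vector", call. = FALSE)
  }
  if (any(concentrations <= 0) || any(!is.finite(concentrations))) {
    stop("internal-standard concentrations must be positive", call. = FALSE)
  }
  structure(as.list(concentrations), class = "is_mix", label = label)
}

#' Absolute concentration by single-point isotope dilution
#'
#' Quantifies an analyte in the original sample from the ratio of its
#' (unlabeled) signal to the signal of a co-processed, fully mass-shifted
#' labeled internal standard of known concentration:
#'
#' `conc = (analyte_signal / is_signal) * is_conc * (mix_volume / sample_volume) * response_factor`
#'
#' The default design mixes equal volumes of sample and standard mix
#' (10 uL + 10 uL), so the volume ratio is 1 and the standard concentration
#' in the mix directly calibrates the sample. The response factor defaults
#' to 1 (identical ionization of labeled and unlabeled species).
#'
#' @param analyte Analyte name (must be present in `mix`).
#' @param analyte_signal Integrated signal of the unlabeled analyte.
#' @param is_signal Integrated signal of the labeled internal standard,
#'   must be positive.
#' @param mix An `is_mix` from [internal_standard_mix()].
#' @param sample_volume_uL,mix_volume_uL Volumes combined, default 10 + 10.
#' @param response_factor Optional per-analyte relative response factor.
#' @return Analyte concentration in the original sample, uM.
#' @export
isotope_dilution_concentration <- function(analyte, analyte_signal, is_signal,
                                           mix, sample_volume_uL = 10,
                                           mix_volume_uL = 10,
                                           response_factor = 1) {
  stopifnot(inherits(mix, "is_mix"))
  if (!analyte %in% names(mix)) {
    stop("analyte '", analyte, "' absent from internal-standard mix",
         call. = FALSE)
  }
  if (is_signal <= 0) {
    stop("internal-standard signal must be positive for quantification",
         call. = FALSE)
  }
  if (analyte_signal < 0) stop("signals must be non-negative", call. = FALSE)
  if (sample_volume_uL <= 0 || mix_volume_uL <= 0) {
    stop("volumes must be positive", call. = FALSE)
  }
  (analyte_signal / is_signal) * mix[[analyte]] *
    (mix_volume_uL / sample_volume_uL) * response_factor
}

#' Quantify a table of isotope-dilution measurements
#'
#' @param measurements Data frame with columns `sample_id`, `analyte`,
#'   `analyte_signal`, `is_signal`, and optionally `sample_volume_uL`,
#'   `mix_volume_uL` (default 10 each).
#' @param mix An `is_mix`.
#' @return The input with an added `conc_uM` column.
#' @export
isotope_dilution_table <- function(measurements, mix) {
  need <- c("sample_id", "analyte", "analyte_signal", "is_signal")
  miss <- setdiff(need, names(measurements))
  if (length(miss) > 0L) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  sv <- measurements$sample_volume_uL %||% rep(10, nrow(measurements))
  mv <- measurements$mix_volume_uL %||% rep(10, nrow(measurements))
  measurements$conc_uM <- vapply(seq_len(nrow(measurements)), function(i) {
    isotope_dilution_concentration(measurements$analyte[i],
                                   measurements$analyte_signal[i],
                                   measurements$is_signal[i], mix,
                                   sv[i], mv[i])
  }, numeric(1))
  measurements
}

#' Tracer spike needed to reach a target enrichment
#'
#' Amount of labeled tracer to add to a medium already containing the
#' unlabeled metabolite at `basal_conc` so that the labeled fraction of the
#' total pool equals `target_enrichment`: solves
#' `spike / (spike + basal) = target`, i.e.
#' `spike = target * basal / (1 - target)`. Used to spike [U-13C5]glutamine
#' into serum to ~33% enrichment.
#'
#' @param basal_conc Pre-existing unlabeled concentration (uM), positive.
#' @param target_enrichment Desired labeled fraction, in (0, 1).
#' @return Tracer concentration to add (uM).
#' @examples
#' spike_to_enrichment(183, 0.33)  # ~90.1 uM
#' @export
spike_to_enrichment <- function(basal_conc, target_enrichment) {
  if (basal_conc <= 0) stop("basal concentration must be positive", call. = FALSE)
  if (target_enrichment <= 0 || target_enrichment >= 1) {
    stop("target enrichment must lie strictly between 0 and 1 ",
         "(spiking cannot exceed full enrichment)", call. = FALSE)
  }
  target_enrichment * basal_conc / (1 - target_enrichment)
}

#' Enrichment realized by a tracer spike
#'
#' Inverse of [spike_to_enrichment()]: the labeled fraction of the pool
#' after adding `spike_conc` of labeled tracer to `basal_conc` of
#' unlabeled metabolite.
#'
#' @param basal_conc Unlabeled concentration (uM), non-negative.
#' @param spike_conc Labeled tracer concentration added (uM), non-negative.
#' @return Enrichment fraction `spike / (basal + spike)`.
#' @export
realized_enrichment <- function(basal_conc, spike_conc) {
  if (basal_conc < 0 || spike_conc < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (basal_conc + spike_conc <= 0) {
    stop("total concentration must be positive", call. = FALSE)
  }
  spike_conc / (basal_conc + spike_conc)
}
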