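#' Specify a synthetic tracer-experiment condition
#'
#' A condition spec collects the ground-truth parameters from which all
#' synthetic tables are generated: tracer enrichment, per-metabolite
#' tracer-derived fractions and labeling kinetics, growth rate, media
#' concentrations and per-cell exchange fluxes, and the noise model.
#'
#' @param label Condition label.
#' @param enrichment Tracer (glutamine) enrichment e in (0, 1).
#' @param fractions Named vector: per metabolite, the ground-truth fraction
#'   g of its pool derived from the tracer, in \[0, 1\].
#' @param shifts Named integer vector of diagnostic mass shifts per
#'   metabolite; defaults to [diagnostic_shifts()].
#' @param tau_hours Named vector of first-order labeling time constants
#'   (hours) per metabolite, for kinetic (pre-steady-state) simulation.
#' @param growth_rate Exponential growth rate per day (natural-log scale).
#' @param n0 Initial cell count.
#' @param media_conc Named vector of initial media concentrations (uM).
#' @param fluxes Named vector of per-cell exchange fluxes (fmol/cell/day;
#'   release positive, consumption negative).
#' @param cv_intensity,cv_counts,cv_quant Multiplicative lognormal noise
#'   CVs for raw MS intensities, cell counts and quantification signals.
#' @param tracer Tracer metabolite name.
#' @param tracer_shift Tracer diagnostic shift.
#' @param seed Integer seed recorded in, and used by, every generator call.
#' @return A `condition_spec` list.
#' @export
condition_spec <- function(label, enrichment, fractions,
                           shifts = diagnostic_shifts(),
                           tau_hours = NULL,
                           growth_rate = log(2) / 2, n0 = 2e4,
                           media_conc = NULL, fluxes = NULL,
                           cv_intensity = 0.05, cv_counts = 0.10,
                           cv_quant = 0.03,
                           tracer = "glutamine", tracer_shift = 5L,
                           seed = 1L) {
  if (enrichment <= 0 || enrichment >= 1) {
    stop("enrichment must lie in (0, 1)", call. = FALSE)
  }
  if (any(fractions < 0 | fractions > 1)) {
    stop("tracer-derived fractions must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(names(fractions))) {
    stop("fractions must be named by metabolite", call. = FALSE)
  }
  if (!tracer %in% names(fractions)) {
    # the tracer pool itself is fully tracer-fed
    fractions <- c(stats::setNames(1, tracer), fractions)
  }
  if (is.null(tau_hours)) {
    tau_hours <- stats::setNames(rep(2, length(fractions)), names(fractions))
  }
  if (any(tau_hours <= 0)) stop("tau_hours must be positive", call. = FALSE)
  if (any(c(cv_intensity, cv_counts, cv_quant) < 0)) {
    stop("noise CVs must be non-negative", call. = FALSE)
  }
  structure(
    list(label = label, enrichment = enrichment, fractions = fractions,
         shifts = shifts, tau_hours = tau_hours,
         growth_rate = growth_rate, n0 = n0,
         media_conc = media_conc, fluxes = fluxes,
         cv_intensity = cv_intensity, cv_counts = cv_counts,
         cv_quant = cv_quant, tracer = tracer,
         tracer_shift = as.integer(tracer_shift), seed = as.integer(seed)),
    class = "condition_spec"
  )
}

#' Built-in condition presets
#'
#' Three presets emulate the qualitative regimes of glutamine tracing in
#' A549-like cells:
#'
#' * `"rpmi"` — standard culture medium with high (~190 uM) cystine:
#'   glutamine dominates TCA anaplerosis (glutamate ~80% glutamine-derived,
#'   other TCA intermediates 60-75%), fast growth (~24 h doubling), fast
#'   label turnover.
#' * `"serum"` — adult-bovine-serum-like medium with trace (~0.3 uM)
#'   cystine: low glutamine contribution (glutamate ~35%, TCA
#'   intermediates 25-30%), slow growth (48 h doubling), slower turnover.
#' * `"serum_cystine"` — serum supplemented with cystine to culture levels
#'   (~208 uM): contribution restored to an intermediate-high level and
#'   turnover accelerated, at serum growth rate.
#'
#' Tracer-derived fractions for glutamate follow the reported ~80% (RPMI)
#' and ~35% (serum) estimates; fractions for the remaining metabolites are
#' interpolated presets chosen to preserve the observed ordering, not
#' estimates of any measured flux. Media concentrations are serum/culture
#' reference values (glutamine 183 uM, glutamate 192 uM, cystine 0.3 uM in
#' serum; RPMI-level amino acids otherwise). Tracer enrichment defaults to
#' 0.33 everywhere.
#'
#' @param preset One of `"rpmi"`, `"serum"`, `"serum_cystine"`.
#' @param seed Integer seed stored in the spec.
#' @param ... Overrides passed to [condition_spec()].
#' @return A `condition_spec`.
#' @examples
#' condition_preset("serum")$growth_rate  # log(2)/2 per day, 48 h doubling
#' @export
condition_preset <- function(preset = c("rpmi", "serum", "serum_cystine"),
                             seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    rpmi = list(
      fractions = c(glutamate = 0.80, "alpha-ketoglutarate" = 0.75,
                    fumarate = 0.65, malate = 0.65, aspartate = 0.62,
                    citrate = 0.60),
      tau = c(glutamine = 0.75, glutamate = 1.5, "alpha-ketoglutarate" = 1.5,
              fumarate = 2, malate = 2, aspartate = 2, citrate = 2.5),
      growth_rate = log(2) / 1,
      media = c(glutamine = 1849, glutamate = 122, cystine = 187),
      fluxes = c(glutamine = -1500, glutamate = 900, cystine = -400)
    ),
    serum = list(
      fractions = c(glutamate = 0.35, "alpha-ketoglutarate" = 0.30,
                    fumarate = 0.28, malate = 0.28, aspartate = 0.25,
                    citrate = 0.25),
      tau = c(glutamine = 1, glutamate = 2.5, "alpha-ketoglutarate" = 2.5,
              fumarate = 3, malate = 3, aspartate = 3, citrate = 3.5),
      growth_rate = log(2) / 2,
      media = c(glutamine = 183, glutamate = 192, cystine = 0.3),
      fluxes = c(glutamine = -300, glutamate = 60, cystine = -3)
    ),
    serum_cystine = list(
      fractions = c(glutamate = 0.65, "alpha-ketoglutarate" = 0.60,
                    fumarate = 0.50, malate = 0.50, aspartate = 0.48,
                    citrate = 0.45),
      tau = c(glutamine = 0.8, glutamate = 1.6, "alpha-ketoglutarate" = 1.6,
              fumarate = 2.2, malate = 2.2, aspartate = 2.2, citrate = 2.6),
      growth_rate = log(2) / 2,
      media = c(glutamine = 183, glutamate = 192, cystine = 208.3),
      fluxes = c(glutamine = -1000, glutamate = 600, cystine = -250)
    )
  )
  fr <- c(stats::setNames(1, "glutamine"), base$fractions)
  fr["glutamine"] <- 1  # the tracer pool itself is fully tracer-fed
  args <- list(label = preset, enrichment = 0.33, fractions = fr,
               tau_hours = base$tau, growth_rate = base$growth_rate,
               media_conc = base$media, fluxes = base$fluxes, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(condition_spec, args)
}

# lognormal multiplicative noise with unit mean and given CV
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate raw labeling data for a condition
#'
#' Generates an uncorrected long-format mass-isotopomer intensity table
#' from a condition spec. For each metabolite the ground-truth
#' tracer-labeled fraction at time t is `g * e * (1 - exp(-t / tau))`
#' (the tracer metabolite itself approaches `e`); `t = Inf` gives
#' isotopic steady state. The true two-component MID (m+0 and the
#' diagnostic shift) is pushed through the fragment's natural-abundance
#' correction matrix to produce the raw envelope the instrument would see,
#' scaled to a nominal total intensity and perturbed with multiplicative
#' lognormal noise per channel.
#'
#' @param spec A `condition_spec`.
#' @param fragments Fragment library; defaults to
#'   [default_fragment_library()].
#' @param timepoints_hr Sampling times in hours; `Inf` (default) for
#'   steady state.
#' @param n_replicates Replicates per timepoint.
#' @param table Isotope abundance table.
#' @param total_intensity Nominal summed raw intensity per fragment.
#' @return List with `raw` (long-format raw intensity table with columns
#'   `sample_id`, `condition`, `metabolite`, `fragment_name`,
#'   `mass_shift`, `value`, plus `replicate` and `time_hr`) and `truth`
#'   (per sample x metabolite ground-truth labeled fractions and
#'   contributions, plus the spec itself as attribute `spec`).
#' @export
simulate_labeling <- function(spec, fragments = default_fragment_library(),
                              timepoints_hr = Inf, n_replicates = 3L,
                              table = default_isotope_table(),
                              total_intensity = 1e6) {
  stopifnot(inherits(spec, "condition_spec"))
  mets <- names(spec$fractions)
  missing <- setdiff(mets, names(fragments))
  if (length(missing) > 0L) {
    stop("no fragment definition for metabolite(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  set.seed(spec$seed)
  mats <- lapply(fragments[mets], build_correction_matrix, table = table)
  raw_rows <- list()
  truth_rows <- list()
  for (t_hr in timepoints_hr) {
    for (rep_i in seq_len(n_replicates)) {
      sid <- paste0(spec$label, "_t", ifelse(is.infinite(t_hr), "ss", t_hr),
                    "_r", rep_i)
      for (met in mets) {
        shift <- if (met %in% names(spec$shifts)) {
          spec$shifts[[met]]
        } else {
          spec$tracer_shift
        }
        g <- spec$fractions[[met]]
        tau <- if (met %in% names(spec$tau_hours)) spec$tau_hours[[met]] else 2
        kin <- if (is.infinite(t_hr)) 1 else 1 - exp(-t_hr / tau)
        f <- g * spec$enrichment * kin
        frag <- fragments[[met]]
        x <- numeric(frag$n_backbone_carbons + 1L)
        x[1] <- 1 - f
        x[shift + 1L] <- x[shift + 1L] + f
        envelope <- as.numeric(unclass(mats[[met]]) %*% x)
        noisy <- envelope * total_intensity *
          lnorm_noise(length(envelope), spec$cv_intensity)
        raw_rows[[length(raw_rows) + 1L]] <- data.frame(
          sample_id = sid, condition = spec$label, replicate = rep_i,
          time_hr = t_hr, metabolite = met,
          fragment_name = frag$fragment_name,
          mass_shift = seq_along(noisy) - 1L, value = noisy)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          sample_id = sid, condition = spec$label, replicate = rep_i,
          time_hr = t_hr, metabolite = met, shift = shift,
          true_labeled_fraction = f,
          true_contribution = g * kin,
          tracer_enrichment = spec$enrichment)
      }
    }
  }
  raw <- do.call(rbind, raw_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(raw) <- rownames(truth) <- NULL
  attr(truth, "spec") <- spec
  list(raw = raw, truth = truth)
}

#' Simulate a cell growth curve
#'
#' Exponential growth `N0 * exp(rate * t)` sampled at the requested days
#' with multiplicative lognormal count noise.
#'
#' @param spec A `condition_spec` (uses `growth_rate`, `n0`, `cv_counts`,
#'   `seed`).
#' @param days Sampling times in days.
#' @param n_replicates Replicate wells per timepoint.
#' @return List with `growth` (columns `culture_id`, `condition`,
#'   `replicate`, `time_days`, `cell_count`) and `truth` (n0, rate,
#'   doubling time).
#' @export
simulate_growth <- function(spec, days = 0:8, n_replicates = 3L) {
  stopifnot(inherits(spec, "condition_spec"))
  set.seed(spec$seed + 1L)
  rows <- list()
  for (rep_i in seq_len(n_replicates)) {
    mu <- spec$n0 * exp(spec$growth_rate * days)
    rows[[rep_i]] <- data.frame(
      culture_id = paste0(spec$label, "_g", rep_i),
      condition = spec$label, replicate = rep_i, time_days = days,
      cell_count = mu * lnorm_noise(length(days), spec$cv_counts))
  }
  growth <- do.call(rbind, rows)
  rownames(growth) <- NULL
  truth <- data.frame(
    condition = spec$label, n0 = spec$n0, rate = spec$growth_rate,
    doubling_time_hours = 24 * log(2) / spec$growth_rate, seed = spec$seed)
  list(growth = growth, truth = truth)
}

#' Simulate a media-exchange experiment
#'
#' Starting from the spec's initial media concentrations, integrates the
#' culture's exponential growth over the interval and moves
#' `flux * cell_days` of each metabolite into or out of the medium; final
#' concentrations floor at zero with a depletion warning. Optional
#' measurement noise applies to both concentration readings.
#'
#' @param spec A `condition_spec` with `media_conc` and `fluxes`.
#' @param volume_mL Medium volume, default 2 mL.
#' @param duration_days Interval length, default 2 days.
#' @param n_replicates Replicate cultures.
#' @param conc_cv Multiplicative CV on measured concentrations, default 0
#'   (noiseless).
#' @return List with `exchanges` (schema of [exchange_rate_table()]),
#'   `growth` (endpoint cell counts per culture) and `truth` (true fluxes
#'   and growth parameters).
#' @export
simulate_media_exchange <- function(spec, volume_mL = 2, duration_days = 2,
                                    n_replicates = 3L, conc_cv = 0) {
  stopifnot(inherits(spec, "condition_spec"))
  if (is.null(spec$media_conc) || is.null(spec$fluxes)) {
    stop("spec must carry media_conc and fluxes", call. = FALSE)
  }
  mets <- intersect(names(spec$fluxes), names(spec$media_conc))
  if (length(mets) == 0L) {
    stop("no metabolite has both a flux and an initial concentration",
         call. = FALSE)
  }
  set.seed(spec$seed + 2L)
  fit <- list(n0 = spec$n0, rate = spec$growth_rate)
  cd <- integrated_cell_days(fit, 0, duration_days)
  xrows <- list(); grows <- list()
  for (rep_i in seq_len(n_replicates)) {
    cid <- paste0(spec$label, "_x", rep_i)
    c0 <- spec$media_conc[mets] * lnorm_noise(length(mets), conc_cv)
    delta <- spec$fluxes[mets] * cd * 1e-9 / (volume_mL / 1000)  # fmol -> uM
    c1 <- (spec$media_conc[mets] + delta) * lnorm_noise(length(mets), conc_cv)
    if (any(c1 < 0)) {
      warning("metabolite(s) depleted below zero in culture ", cid, ": ",
              paste(mets[c1 < 0], collapse = ", "),
              "; clipping to 0 (nutrient exhaustion)", call. = FALSE)
      c1 <- pmax(c1, 0)
    }
    xrows[[rep_i]] <- data.frame(
      culture_id = cid, condition = spec$label, metabolite = mets,
      conc_initial_uM = unname(c0), conc_final_uM = unname(c1),
      volume_mL = volume_mL, t0_days = 0, t1_days = duration_days)
    grows[[rep_i]] <- data.frame(
      culture_id = cid, condition = spec$label,
      time_days = c(0, duration_days),
      cell_count = spec$n0 * exp(spec$growth_rate * c(0, duration_days)))
  }
  truth <- data.frame(condition = spec$label, metabolite = mets,
                      flux_fmol_per_cell_per_day = unname(spec$fluxes[mets]),
                      n0 = spec$n0, rate = spec$growth_rate,
                      cell_days = cd, seed = spec$seed)
  out_x <- do.call(rbind, xrows); rownames(out_x) <- NULL
  out_g <- do.call(rbind, grows); rownames(out_g) <- NULL
  list(exchanges = out_x, growth = out_g, truth = truth)
}

#' Simulate isotope-dilution quantification signals
#'
#' Emits analyte/internal-standard peak-area pairs consistent with the
#' spec's true media concentrations, the mix's standard concentrations and
#' the stated volumes, with multiplicative signal noise at `cv_quant`.
#'
#' @param spec A `condition_spec` with `media_conc` (true concentrations).
#' @param mix An `is_mix`; must cover the spec's analytes.
#' @param n_samples Number of replicate samples.
#' @param sample_volume_uL,mix_volume_uL Mixing volumes, default 10 + 10.
#' @param base_signal Nominal internal-standard peak area.
#' @return List with `measurements` (schema of [isotope_dilution_table()])
#'   and `truth` (true concentrations).
#' @export
simulate_quant <- function(spec, mix, n_samples = 3L,
                           sample_volume_uL = 10, mix_volume_uL = 10,
                           base_signal = 1e5) {
  stopifnot(inherits(spec, "condition_spec"), inherits(mix, "is_mix"))
  if (is.null(spec$media_conc)) {
    stop("spec must carry media_conc", call. = FALSE)
  }
  analytes <- names(spec$media_conc)
  missing <- setdiff(analytes, names(mix))
  if (length(missing) > 0L) {
    stop("internal-standard mix lacks analyte(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  set.seed(spec$seed + 3L)
  rows <- list()
  for (s in seq_len(n_samples)) {
    sid <- paste0(spec$label, "_q", s)
    is_sig <- base_signal * lnorm_noise(length(analytes), spec$cv_quant)
    ratio_true <- (spec$media_conc[analytes] * sample_volume_uL) /
      (vapply(analytes, function(a) mix[[a]], numeric(1)) * mix_volume_uL)
    an_sig <- base_signal * ratio_true *
      lnorm_noise(length(analytes), spec$cv_quant)
    rows[[s]] <- data.frame(
      sample_id = sid, condition = spec$label, analyte = analytes,
      analyte_signal = unname(an_sig), is_signal = unname(is_sig),
      sample_volume_uL = sample_volume_uL, mix_volume_uL = mix_volume_uL)
  }
  meas <- do.call(rbind, rows)
  rownames(meas) <- NULL
  truth <- data.frame(condition = spec$label, analyte = analytes,
                      true_conc_uM = unname(spec$media_conc[analytes]),
                      seed = spec$seed)
  rownames(truth) <- NULL
  list(measurements = meas, truth = truth)
}
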