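#' Diagnostic mass shifts for oxidative glutamine tracing
#'
#' With a [U-13C5]glutamine tracer metabolized oxidatively, intact
#' five-carbon skeletons appear as m+5 in glutamine, glutamate and
#' alpha-ketoglutarate, while one oxidative decarboxylation leaves m+4
#' species in fumarate, malate, aspartate and citrate. These are the mass
#' shifts read out as "fractional labeling" for each metabolite.
#'
#' @return Named integer vector mapping metabolite to its diagnostic shift.
#' @export
diagnostic_shifts <- function() {
  c(glutamine = 5L, glutamate = 5L, "alpha-ketoglutarate" = 5L,
    fumarate = 4L, malate = 4L, aspartate = 4L, citrate = 4L)
}

#' Fractional labeling at a mass shift
#'
#' Reads the fraction of a corrected MID at the requested mass shift, e.g.
#' the m+5 fraction of glutamate.
#'
#' @param mid A `mid` object (or plain fraction vector over m+0..m+n).
#' @param shift Integer mass shift (0-based).
#' @return Fraction in \[0, 1\].
#' @export
fractional_labeling <- function(mid, shift) {
  x <- as.numeric(mid)
  if (!is.numeric(shift) || length(shift) != 1L || shift != round(shift)) {
    stop("shift must be a single integer", call. = FALSE)
  }
  if (shift < 0 || shift > length(x) - 1L) {
    stop("mass shift ", shift, " outside measured range m+0..m+",
         length(x) - 1L, call. = FALSE)
  }
  x[shift + 1L]
}

#' Normalized contribution of the tracer to a metabolite pool
#'
#' Divides a metabolite's diagnostic-shift fractional labeling by the
#' tracer's fractional enrichment in the same sample. Under a well-mixed
#' precursor-product model this ratio estimates the fraction of the
#' metabolite pool derived from the tracer substrate: e.g. glutamate m+5 of
#' 0.27 over glutamine m+5 enrichment of 0.33 gives 0.818, i.e. about 80%
#' of glutamate carbon comes from glutamine.
#'
#' @param metabolite_mid Corrected MID of the metabolite.
#' @param metabolite_shift Diagnostic shift of the metabolite (5 pre-, 4
#'   post-decarboxylation for glutamine tracing).
#' @param tracer_mid Corrected MID of the tracer metabolite (glutamine).
#' @param tracer_shift Diagnostic shift of the tracer, default 5.
#' @return Contribution fraction (typically in \[0, 1\]; can slightly exceed
#'   1 under measurement noise).
#' @export
normalized_contribution <- function(metabolite_mid, metabolite_shift,
                                    tracer_mid, tracer_shift = 5L) {
  num <- fractional_labeling(metabolite_mid, metabolite_shift)
  den <- fractional_labeling(tracer_mid, tracer_shift)
  if (den <= 0) {
    stop("tracer fractional labeling is zero; normalized contribution is ",
         "undefined", call. = FALSE)
  }
  num / den
}

#' Summarize fractional labeling and contributions by condition
#'
#' Collapses a corrected long-format MID table to per-condition,
#' per-metabolite summaries: mean and SD of diagnostic-shift fractional
#' labeling across replicates, replicate count, and per-replicate
#' tracer-normalized contributions.
#'
#' @param corrected Long-format corrected MID table (columns `sample_id`,
#'   `condition`, `metabolite`, `fragment_name`, `mass_shift`, `value`).
#' @param tracer Name of the tracer metabolite, default `"glutamine"`.
#' @param tracer_shift Tracer diagnostic shift, default 5.
#' @param shifts Named integer vector of diagnostic shifts per metabolite;
#'   defaults to [diagnostic_shifts()]. Metabolites absent from `shifts`
#'   default to their maximum measured shift.
#' @return A `condition_summary` data frame with one row per condition x
#'   metabolite: columns `condition`, `metabolite`, `shift`, `n`,
#'   `mean_labeling`, `sd_labeling`, `mean_enrichment`,
#'   `mean_contribution`, `sd_contribution`, plus the per-replicate
#'   contributions in attribute `replicates`.
#' @export
condition_summary <- function(corrected, tracer = "glutamine",
                              tracer_shift = 5L,
                              shifts = diagnostic_shifts()) {
  validate_mid_table(corrected)
  if (!tracer %in% corrected$metabolite) {
    stop("tracer metabolite '", tracer, "' absent from table", call. = FALSE)
  }
  per_rep <- replicate_labeling(corrected, tracer, tracer_shift, shifts)
  agg <- function(v) c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0)
  groups <- split(per_rep, interaction(per_rep$condition, per_rep$metabolite,
                                       drop = TRUE))
  rows <- lapply(groups, function(g) {
    data.frame(condition = g$condition[1], metabolite = g$metabolite[1],
               shift = g$shift[1], n = nrow(g),
               mean_labeling = mean(g$labeling),
               sd_labeling = if (nrow(g) > 1L) stats::sd(g$labeling) else 0,
               mean_enrichment = mean(g$enrichment),
               mean_contribution = mean(g$contribution),
               sd_contribution = if (nrow(g) > 1L) stats::sd(g$contribution) else 0)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$metabolite), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("condition_summary", "data.frame"),
            replicates = per_rep, tracer = tracer, tracer_shift = tracer_shift)
}

# per-sample diagnostic-shift labeling, tracer enrichment and contribution
replicate_labeling <- function(corrected, tracer, tracer_shift, shifts) {
  key <- interaction(corrected$sample_id, corrected$metabolite, drop = TRUE)
  recs <- lapply(split(corrected, key), function(g) {
    g <- g[order(g$mass_shift), , drop = FALSE]
    met <- g$metabolite[1]
    shift <- if (met %in% names(shifts)) shifts[[met]] else max(g$mass_shift)
    if (shift > max(g$mass_shift)) {
      stop("diagnostic shift m+", shift, " for ", met,
           " exceeds measured range", call. = FALSE)
    }
    data.frame(sample_id = g$sample_id[1], condition = g$condition[1],
               metabolite = met, shift = shift,
               labeling = g$value[g$mass_shift == shift])
  })
  per <- do.call(rbind, recs)
  trc <- per[per$metabolite == tracer & per$shift == tracer_shift, ,
             drop = FALSE]
  if (nrow(trc) == 0L) {
    # tracer read out at tracer_shift even if its library shift differs
    trc_rows <- corrected$metabolite == tracer &
      corrected$mass_shift == tracer_shift
    trc <- corrected[trc_rows, c("sample_id", "value")]
    names(trc)[2] <- "labeling"
  }
  enr <- stats::setNames(trc$labeling, trc$sample_id)
  per$enrichment <- enr[as.character(per$sample_id)]
  if (any(is.na(per$enrichment))) {
    stop("tracer MID missing for sample(s): ",
         paste(unique(per$sample_id[is.na(per$enrichment)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(per$enrichment <= 0)) {
    stop("tracer enrichment is zero in sample(s): ",
         paste(unique(per$sample_id[per$enrichment <= 0]), collapse = ", "),
         call. = FALSE)
  }
  per$contribution <- per$labeling / per$enrichment
  rownames(per) <- NULL
  per
}

#' Condition contrast of tracer contribution (cystine-induced increase)
#'
#' Computes the difference in mean tracer-normalized contribution of a
#' target metabolite between a high and a low condition — the statistic
#' used to quantify how much a nutrient (cystine) enhances glutamine
#' anaplerosis: the difference in m+5 fractional labeling of
#' alpha-ketoglutarate, normalized to glutamine m+5 enrichment, between the
#' cystine-supplemented and the basal condition.
#'
#' @param summary_high `condition_summary` (or the combined summary) for
#'   the high condition, or a single `condition_summary` covering both
#'   conditions.
#' @param high,low Condition labels to contrast (high minus low). If
#'   `summary_high` covers only one condition each, labels are inferred.
#' @param metabolite Target metabolite, default `"alpha-ketoglutarate"`.
#' @return A `condition_comparison` list: `statistic` (mean high minus mean
#'   low contribution), `metabolite`, `high`, `low`, per-replicate
#'   contribution vectors `contributions_high` / `contributions_low`, and
#'   the two-tailed unpaired t-test on the replicate contributions (when
#'   both groups have at least two replicates).
#' @export
cystine_induced_increase <- function(summary_high, high = NULL, low = NULL,
                                     metabolite = "alpha-ketoglutarate") {
  stopifnot(inherits(summary_high, "condition_summary"))
  reps <- attr(summary_high, "replicates")
  conds <- unique(reps$condition)
  if (is.null(high) || is.null(low)) {
    if (length(conds) != 2L) {
      stop("specify 'high' and 'low' condition labels (found conditions: ",
           paste(conds, collapse = ", "), ")", call. = FALSE)
    }
    high <- high %||% conds[1]
    low <- low %||% conds[2]
  }
  pick <- function(cond) {
    v <- reps$contribution[reps$condition == cond & reps$metabolite == metabolite]
    if (length(v) == 0L) {
      stop("metabolite '", metabolite, "' not found in condition '", cond, "'",
           call. = FALSE)
    }
    v
  }
  ch <- pick(high)
  cl <- pick(low)
  tt <- if (length(ch) >= 2L && length(cl) >= 2L) {
    unpaired_t_test(ch, cl)
  } else {
    NULL
  }
  structure(
    list(statistic = mean(ch) - mean(cl), metabolite = metabolite,
         high = high, low = low,
         contributions_high = ch, contributions_low = cl, t_test = tt),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison> ", x$metabolite, ": ", x$high, " - ", x$low,
      " = ", format(round(x$statistic, 4)), "\n", sep = "")
  if (!is.null(x$t_test)) {
    cat("  t = ", format(round(x$t_test$statistic, 3)),
        ", df = ", format(round(x$t_test$df, 2)),
        ", p = ", format.pval(x$t_test$p_value, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Check a labeling time course for isotopic steady state
#'
#' A series is declared steady from the first observed time point whose
#' arrival was accompanied by a relative change at most `rel_tol` and after
#' which every successive relative change also stays within `rel_tol`. A
#' series that never changes is steady from its first point.
#'
#' @param times Strictly increasing numeric time points (hours).
#' @param values Fractional labeling at each time point.
#' @param rel_tol Maximum successive relative change, default 0.05.
#' @return List with `steady` (logical), `time` (time of attainment or NA)
#'   and `index` (index of attainment or NA).
#' @export
steady_state_check <- function(times, values, rel_tol = 0.05) {
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("steady-state check needs at least two time points", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  prev <- values[-length(values)]
  rel <- abs(diff(values)) / ifelse(prev == 0, .Machine$double.eps, abs(prev))
  ok <- rel <= rel_tol
  if (all(rel == 0)) {
    return(list(steady = TRUE, time = times[1], index = 1L))
  }
  # first transition index k such that transitions k..end are all within tol
  runs <- rev(cumprod(rev(ok)))
  k <- which(runs == 1)[1]
  if (is.na(k)) {
    list(steady = FALSE, time = NA_real_, index = NA_integer_)
  } else {
    list(steady = TRUE, time = times[k + 1L], index = k + 1L)
  }
}

#' Two-sample unpaired t-test
#'
#' Thin wrapper around [stats::t.test()] defaulting to the two-tailed
#' equal-variance (Student) flavor typical of n = 3 tracing designs, with
#' Welch's unequal-variance test available via `var_equal = FALSE`. The
#' degenerate case of two identical zero-variance groups returns t = 0,
#' p = 1 by convention rather than erroring.
#'
#' @param group_a,group_b Numeric vectors, each of length at least 2.
#' @param var_equal Pool the variance (Student) when `TRUE` (default);
#'   Welch otherwise.
#' @param two_tailed Two-sided p-value (default `TRUE`).
#' @return List with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
unpaired_t_test <- function(group_a, group_b, var_equal = TRUE,
                            two_tailed = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    # degenerate zero-variance cases resolved by convention
    df0 <- length(group_a) + length(group_b) - 2L
    d <- mean(group_a) - mean(group_b)
    if (d == 0) {
      return(list(statistic = 0, df = df0, p_value = 1,
                  mean_a = mean(group_a), mean_b = mean(group_b)))
    }
    return(list(statistic = sign(d) * Inf, df = df0, p_value = 0,
                mean_a = mean(group_a), mean_b = mean(group_b)))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal,
                      alternative = if (two_tailed) "two.sided" else "greater")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}
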