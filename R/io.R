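#' Read a long-format MID table from CSV
#'
#' Reads and validates a raw or corrected mass-isotopomer table. Required
#' columns: `sample_id`, `condition`, `metabolite`, `fragment_name`,
#' `mass_shift`, `value`. Mass shifts within each (sample, metabolite,
#' fragment) group must be consecutive integers starting at 0, with no
#' duplicates.
#'
#' @param path Path to a CSV file.
#' @return Validated data frame.
#' @export
read_mid_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_mid_table(df)
  df
}

#' Write a long-format MID table to CSV
#'
#' @param table Data frame passing [validate_mid_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mid_table <- function(table, path) {
  validate_mid_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a long-format MID table
#'
#' @param df Data frame to validate (see [read_mid_table()] for schema).
#' @return `df`, invisibly; errors describe the first violation found.
#' @export
validate_mid_table <- function(df) {
  need <- c("sample_id", "condition", "metabolite", "fragment_name",
            "mass_shift", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("MID table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$mass_shift) || !is.numeric(df$value)) {
    stop("mass_shift and value must be numeric", call. = FALSE)
  }
  if (any(!is.finite(df$value)) || any(df$value < 0)) {
    stop("MID values must be finite and non-negative", call. = FALSE)
  }
  key <- interaction(df$sample_id, df$metabolite, df$fragment_name,
                     drop = TRUE)
  for (g in split(df, key)) {
    s <- sort(g$mass_shift)
    if (anyDuplicated(s)) {
      stop("duplicate mass shift ", s[which(duplicated(s))[1]],
           " for sample '", g$sample_id[1], "', fragment '",
           g$fragment_name[1], "'", call. = FALSE)
    }
    expect <- seq(0L, length(s) - 1L)
    if (!identical(as.integer(s), expect)) {
      gap <- setdiff(expect, s)
      stop("mass shifts for sample '", g$sample_id[1], "', fragment '",
           g$fragment_name[1], "' are not consecutive from 0",
           if (length(gap) > 0L) paste0(" (missing shift ", gap[1], ")"),
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Read an experiment configuration file
#'
#' The configuration is a single YAML file naming the tracer, the
#' comparisons to run and analysis options. Recognized keys: `tracer`
#' (name, default glutamine), `tracer_shift` (default 5), `comparisons`
#' (list of `{high, low, metabolite}` mappings), `steady_state_tol`
#' (default 0.05), `t_test` (`"student"` or `"welch"`), `fragments`
#' (path to a fragment-library TSV) and `abundances` (path to an isotope
#' abundance YAML).
#'
#' @param path Path to a YAML configuration file.
#' @return An `experiment_config` list with defaults filled in.
#' @export
read_experiment_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  experiment_config(
    tracer = raw$tracer %||% "glutamine",
    tracer_shift = as.integer(raw$tracer_shift %||% 5L),
    comparisons = raw$comparisons %||% list(),
    steady_state_tol = raw$steady_state_tol %||% 0.05,
    t_test = raw$t_test %||% "student",
    fragments = raw$fragments, abundances = raw$abundances
  )
}

#' Construct an experiment configuration
#'
#' @param tracer Tracer metabolite name.
#' @param tracer_shift Tracer diagnostic mass shift.
#' @param comparisons List of comparisons, each a list with elements
#'   `high`, `low` and optionally `metabolite` (default
#'   alpha-ketoglutarate).
#' @param steady_state_tol Relative tolerance for steady-state checks.
#' @param t_test `"student"` (equal variance, default) or `"welch"`.
#' @param fragments Optional path to a fragment-library TSV.
#' @param abundances Optional path to an abundance-table YAML.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(tracer = "glutamine", tracer_shift = 5L,
                              comparisons = list(), steady_state_tol = 0.05,
                              t_test = c("student", "welch"),
                              fragments = NULL, abundances = NULL) {
  t_test <- match.arg(t_test)
  structure(
    list(tracer = tracer, tracer_shift = as.integer(tracer_shift),
         comparisons = comparisons, steady_state_tol = steady_state_tol,
         t_test = t_test, fragments = fragments, abundances = abundances),
    class = "experiment_config"
  )
}

#' Run the full tracing analysis pipeline
#'
#' Orchestrates correction, per-condition summaries, condition comparisons
#' and (optionally) rate and quantification analyses from file paths or
#' in-memory tables, writing all intermediate CSVs and a plain-text report
#' when `out_dir` is given. The run is deterministic given its inputs.
#'
#' @param raw_mids Path to a raw MID CSV, or an equivalent data frame.
#' @param config An `experiment_config`, or a path to a YAML config file,
#'   or `NULL` for defaults (no comparisons).
#' @param growth Optional growth-curve table/CSV (`culture_id`,
#'   `time_days`, `cell_count`).
#' @param exchanges Optional exchange table/CSV (see
#'   [exchange_rate_table()]).
#' @param quant Optional quantification table/CSV (see
#'   [isotope_dilution_table()]), requires `mix`.
#' @param mix Optional `is_mix` for quantification.
#' @param out_dir Optional output directory for CSVs and the report.
#' @return A `run_report` list: `corrected`, `summary`, `comparisons`,
#'   `rates`, `quant`, `provenance`.
#' @export
run_pipeline <- function(raw_mids, config = NULL, growth = NULL,
                         exchanges = NULL, quant = NULL, mix = NULL,
                         out_dir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  if (is.null(config)) config <- experiment_config()
  raw <- if (is.character(raw_mids)) read_mid_table(raw_mids) else {
    validate_mid_table(raw_mids); raw_mids
  }
  fragments <- if (!is.null(config$fragments)) {
    read_fragment_library(config$fragments)
  } else {
    default_fragment_library()
  }
  abundances <- if (!is.null(config$abundances)) {
    read_isotope_table(config$abundances)
  } else {
    default_isotope_table()
  }

  corrected <- with_stage("correct", correct_mid_table(
    raw, fragments = fragments, table = abundances))
  summ <- with_stage("summarize", condition_summary(
    corrected, tracer = config$tracer, tracer_shift = config$tracer_shift))
  comparisons <- lapply(config$comparisons, function(cmp) {
    with_stage("compare", cystine_induced_increase(
      summ, high = cmp$high, low = cmp$low,
      metabolite = cmp$metabolite %||% "alpha-ketoglutarate"))
  })
  rates <- if (!is.null(growth) && !is.null(exchanges)) {
    g <- if (is.character(growth)) utils::read.csv(growth) else growth
    x <- if (is.character(exchanges)) utils::read.csv(exchanges) else exchanges
    with_stage("rates", exchange_rate_table(x, g))
  }
  quant_out <- if (!is.null(quant)) {
    if (is.null(mix)) stop("quantification requires an internal-standard mix",
                           call. = FALSE)
    q <- if (is.character(quant)) utils::read.csv(quant) else quant
    with_stage("quant", isotope_dilution_table(q, mix))
  }

  report <- structure(
    list(corrected = corrected, summary = summ, comparisons = comparisons,
         rates = rates, quant = quant_out,
         provenance = list(
           tool = "tracemet",
           version = as.character(utils::packageVersion("tracemet")),
           config = unclass(config),
           n_samples = length(unique(raw$sample_id)))),
    class = "run_report"
  )
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

# tag stage errors with the pipeline stage that raised them
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Write a run report to a directory
#'
#' Writes `corrected_mids.csv`, `condition_summary.csv`,
#' `comparisons.csv`, and when present `rates.csv` and `quant.csv`, plus a
#' plain-text `report.txt`.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mid_table(report$corrected, file.path(out_dir, "corrected_mids.csv"))
  utils::write.csv(as.data.frame(report$summary),
                   file.path(out_dir, "condition_summary.csv"),
                   row.names = FALSE)
  if (length(report$comparisons) > 0L) {
    cmp_df <- do.call(rbind, lapply(report$comparisons, function(x) {
      data.frame(metabolite = x$metabolite, high = x$high, low = x$low,
                 statistic = x$statistic,
                 t = if (!is.null(x$t_test)) x$t_test$statistic else NA,
                 df = if (!is.null(x$t_test)) x$t_test$df else NA,
                 p_value = if (!is.null(x$t_test)) x$t_test$p_value else NA)
    }))
    utils::write.csv(cmp_df, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$rates)) {
    utils::write.csv(report$rates, file.path(out_dir, "rates.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$quant)) {
    utils::write.csv(report$quant, file.path(out_dir, "quant.csv"),
                     row.names = FALSE)
  }
  writeLines(format_run_report(report), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

format_run_report <- function(report) {
  lines <- c(
    paste0("tracemet run report (v", report$provenance$version, ")"),
    paste0("samples: ", report$provenance$n_samples),
    "",
    "Per-condition tracer contributions (mean +/- SD):")
  s <- as.data.frame(report$summary)
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "  %-16s %-22s m+%d labeling %.3f+/-%.3f  contribution %.3f+/-%.3f (n=%d)",
      s$condition[i], s$metabolite[i], s$shift[i], s$mean_labeling[i],
      s$sd_labeling[i], s$mean_contribution[i], s$sd_contribution[i], s$n[i]))
  }
  for (cmp in report$comparisons) {
    lines <- c(lines, "", sprintf(
      "Contrast %s: %s - %s = %.4f", cmp$metabolite, cmp$high, cmp$low,
      cmp$statistic))
    if (!is.null(cmp$t_test)) {
      lines <- c(lines, sprintf("  t = %.3f, df = %.1f, p = %.4g",
                                cmp$t_test$statistic, cmp$t_test$df,
                                cmp$t_test$p_value))
    }
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(format_run_report(x), sep = "\n")
  invisible(x)
}
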