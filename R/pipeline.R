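#' Read or write box-level bioassay records
#'
#' Comma-separated text with a header row and columns `year`,
#' `cultivar`, `life_stage`, `replicate`, `duration_days`, `unit_id`,
#' `pupae_count`, and optionally `treated_estimate`.
#'
#' @param path CSV file path.
#' @param data Data frame of records.
#' @return `read_observations()` a data frame; `write_observations()`
#'   `path`, invisibly.
#' @export
read_observations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_observations
#' @export
write_observations <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate bioassay input records
#'
#' Schema, type, and range diagnostics for box-level records. Returns a
#' zero-row data frame when the input is clean (generator outputs are).
#'
#' @param data A data frame or a path to a CSV file.
#' @return Data frame with columns `severity` (`"error"`/`"warning"`),
#'   `row` (NA for file-level problems), `column`, `problem`.
#' @export
validate_observations <- function(data) {
  if (is.character(data)) data <- read_observations(data)
  diag <- data.frame(severity = character(0), row = integer(0),
                     column = character(0), problem = character(0),
                     stringsAsFactors = FALSE)
  add <- function(severity, row, column, problem) {
    rbind(diag, data.frame(severity = severity, row = row, column = column,
                           problem = problem, stringsAsFactors = FALSE))
  }
  need <- c("year", "cultivar", "life_stage", "replicate", "duration_days",
            "unit_id", "pupae_count")
  for (col in setdiff(need, names(data))) {
    diag <- add("error", NA_integer_, col, "missing column")
  }
  if (nrow(diag)) return(diag)
  bad <- which(!is.finite(data$pupae_count) | data$pupae_count < 0)
  for (i in bad) diag <- add("error", i, "pupae_count", "negative or non-numeric count")
  bad <- which(!is.finite(data$duration_days) | data$duration_days < 0)
  for (i in bad) diag <- add("error", i, "duration_days", "negative or non-numeric duration")
  if ("treated_estimate" %in% names(data)) {
    bad <- which(!is.finite(data$treated_estimate) | data$treated_estimate <= 0)
    for (i in bad) diag <- add("error", i, "treated_estimate", "non-positive estimate")
  }
  key <- paste(data$cultivar, data$life_stage, data$replicate,
               data$duration_days, data$unit_id)
  dup <- which(duplicated(key))
  for (i in dup) diag <- add("warning", i, "unit_id", "duplicated unit within group")
  diag
}

#' Run the full cold-treatment analysis pipeline
#'
#' Validates the inputs, completes treated-number bookkeeping from
#' control boxes, summarises group mortalities, fits the beta-binomial
#' time-mortality model, tabulates lethal times with Fieller intervals,
#' and (when the corresponding inputs are given) evaluates large-scale
#' efficacy and temperature-profile QA. All outputs are written as
#' delimited text or JSON under `out_dir`; the pipeline is a pure
#' function of its inputs, configuration, and seed.
#'
#' @param data Box-level records (data frame or CSV path).
#' @param out_dir Output directory (created if needed).
#' @param link `"auto"`, `"logit"`, or `"probit"`.
#' @param levels Mortality levels for the lethal-time table (default
#'   50%, 95%, 99%, and probit 9).
#' @param level Confidence level (default 0.95).
#' @param random Random-effect structure passed to [bb_model_spec()].
#' @param control_counts,n_control_fruit,n_treated_fruit,survivors
#'   Optional large-scale-trial inputs for [efficacy_report()].
#' @param thermal_log Optional temperature log (data frame or CSV path)
#'   for [profile_summary()].
#' @param seed Seed for the dispersion diagnostic.
#'
#' @return A list with the fitted model, lethal-time table, mortality
#'   summary, dispersion check, and any efficacy/thermal results,
#'   invisibly. Side effects: `mortality_summary.tsv`, `fit.json`,
#'   `lt_table.tsv`, `lt_table.csv`, `report.json`, `run.log`, and when
#'   applicable `efficacy.json` and `thermal_summary.tsv` in `out_dir`.
#' @export
run_cold_analysis <- function(data, out_dir, link = "auto",
                              levels = c(0.5, 0.95, 0.99, probit9),
                              level = 0.95, random = "none",
                              control_counts = NULL, n_control_fruit = NULL,
                              n_treated_fruit = NULL, survivors = 0,
                              thermal_log = NULL, seed = 1) {
  if (is.character(data)) data <- read_observations(data)
  if (any(levels <= 0 | levels >= 1)) {
    stop("mortality `levels` must lie in (0, 1)", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logpath <- file.path(out_dir, "run.log")
  logcon <- file(logpath, open = "wt")
  on.exit(close(logcon))
  say <- function(...) writeLines(sprintf(...), logcon)
  say("records: %d", nrow(data))
  diag <- validate_observations(data)
  if (any(diag$severity == "error")) {
    bad <- diag[diag$severity == "error", ]
    stop("invalid input rows: ",
         paste(sprintf("row %s %s (%s)", bad$row, bad$column, bad$problem),
               collapse = "; "), call. = FALSE)
  }
  if (nrow(diag)) say("validation warnings: %d", nrow(diag))
  if (!"treated_estimate" %in% names(data)) data <- estimate_treated(data)
  summ <- summarize_mortality(data)
  write_mortality_table(summ, file.path(out_dir, "mortality_summary.tsv"))
  spec <- bb_model_spec(link = link, random = random)
  fit <- fit_time_mortality(data, spec)
  say("fit: link=%s loglik=%.4f converged=%s", fit$spec$link, fit$loglik,
      fit$converged)
  if (!fit$converged) stop("model fit did not converge", call. = FALSE)
  write_fit(fit, file.path(out_dir, "fit.json"))
  lt <- lt_table(fit, ps = levels, level = level)
  write_lt_table(lt, file.path(out_dir, "lt_table.tsv"))
  utils::write.csv(lt, file.path(out_dir, "lt_table.csv"), row.names = FALSE)
  dc <- dispersion_check(fit, n_sim = 200, seed = seed)
  say("dispersion: statistic=%.3f p=%.3f", dc$dispersion_statistic, dc$p_value)
  eff <- NULL
  if (!is.null(control_counts)) {
    eff <- efficacy_report(control_counts, n_control_fruit, n_treated_fruit,
                           survivors = survivors, level = level,
                           path = file.path(out_dir, "efficacy.json"))
    say("efficacy: n_treated=%d confidence=%.6f", eff$n_treated, eff$confidence)
  }
  thermal <- NULL
  if (!is.null(thermal_log)) {
    if (is.character(thermal_log)) thermal_log <- read_temperature_log(thermal_log)
    thermal <- profile_summary(thermal_log)
    utils::write.table(thermal, file.path(out_dir, "thermal_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("thermal: cooldown=%.2f h constancy=%.1f%%",
        thermal$cooldown_hours, thermal$constancy_pct)
  }
  report <- list(
    n_obs = nrow(data), link = fit$spec$link, loglik = fit$loglik,
    aic = fit$aic, converged = fit$converged,
    coefficients = as.list(fit$coefficients),
    dispersion_check = dc,
    lt_table = lt,
    efficacy = if (!is.null(eff)) eff[c("n_treated", "confidence", "policy")],
    thermal = thermal)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(fit = fit, lt_table = lt, summary = summ,
                 dispersion_check = dc, efficacy = eff, thermal = thermal,
                 diagnostics = diag))
}
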