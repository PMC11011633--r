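#' Expected untreated totals from control boxes
#'
#' Assigns to every treated unit an estimated number treated `E`: the
#' mean pupal count of the control (duration 0) units in the matching
#' cultivar x replicate x life-stage group. This is the denominator used
#' to convert pupal counts to proportional mortality.
#'
#' @param data Data frame of box-level records with columns `cultivar`,
#'   `replicate`, `life_stage`, `duration_days`, `pupae_count`.
#' @param by Grouping columns used to match controls (default
#'   `c("cultivar", "replicate", "life_stage")`).
#'
#' @return `data` with a `treated_estimate` column added (controls get
#'   their own group mean too, so they can enter the model as data
#'   points).
#' @export
estimate_treated <- function(data, by = c("cultivar", "replicate", "life_stage")) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(by, "duration_days", "pupae_count"), names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(data[by], sep = "\r"))
  ctrl <- data$duration_days == 0
  if (!any(ctrl)) stop("no control (duration 0) units in data", call. = FALSE)
  means <- tapply(data$pupae_count[ctrl], key[ctrl], mean)
  e <- unname(means[key])
  if (anyNA(e)) {
    bad <- unique(gsub("\r", " / ", key[is.na(e)]))
    stop("no matching control units for group(s): ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  data$treated_estimate <- as.numeric(e)
  data
}

#' Convert pupal counts to proportional mortality
#'
#' `max(0, 1 - pupae / expected)`, clipped to `[0, 1]`: boxes that yield
#' more pupae than expected (survival exceeding the control-based
#' expectation) are recorded as 0% mortality.
#'
#' @param pupae Pupae retrieved (non-negative).
#' @param expected Estimated number treated (positive).
#' @return Proportion dead in `[0, 1]`.
#' @export
mortality_from_counts <- function(pupae, expected) {
  if (any(expected <= 0)) stop("`expected` must be positive", call. = FALSE)
  if (any(pupae < 0)) stop("`pupae` must be non-negative", call. = FALSE)
  pmin(pmax(1 - pupae / expected, 0), 1)
}

#' Group mortality summaries
#'
#' Produces the per-group bookkeeping used in bioassay summary tables:
#' number of units `N`, total pupae retrieved `P`, total estimated
#' treated `E`, median mortality `M` (%) and mortality range `R` (%),
#' with the box as the summary unit and percentages to one decimal.
#'
#' @param data Data frame with `pupae_count`, `treated_estimate`, and the
#'   grouping columns.
#' @param by Grouping columns (default cultivar, life stage, duration).
#'
#' @return A data frame with columns `by`, `n_units`, `pupae_total`,
#'   `treated_total`, `median_mortality`, `mortality_min`,
#'   `mortality_max` (mortalities in percent).
#' @export
summarize_mortality <- function(data,
                                by = c("cultivar", "life_stage", "duration_days")) {
  data <- as.data.frame(data)
  if (!"treated_estimate" %in% names(data)) data <- estimate_treated(data)
  mort <- mortality_from_counts(data$pupae_count, data$treated_estimate)
  key <- do.call(paste, c(data[by], sep = "\r"))
  groups <- split(seq_len(nrow(data)), key)
  rows <- lapply(groups, function(idx) {
    g <- data[idx[1], by, drop = FALSE]
    g$n_units <- length(idx)
    g$pupae_total <- sum(data$pupae_count[idx])
    g$treated_total <- sum(data$treated_estimate[idx])
    g$median_mortality <- round(100 * stats::median(mort[idx]), 1)
    g$mortality_min <- round(100 * min(mort[idx]), 1)
    g$mortality_max <- round(100 * max(mort[idx]), 1)
    g
  })
  out <- do.call(rbind, rows)
  ord <- do.call(order, out[by])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a mortality summary as delimited text
#'
#' Tab-separated table in the D / N / P / E / M / R column layout, one
#' block per cultivar and stage.
#'
#' @param x A [summarize_mortality()] result.
#' @param path Output file path.
#' @return `x` invisibly.
#' @export
write_mortality_table <- function(x, path) {
  out <- data.frame(cultivar = x$cultivar, life_stage = x$life_stage,
                    D = x$duration_days, N = x$n_units, P = x$pupae_total,
                    E = round(x$treated_total),
                    M = x$median_mortality,
                    R = sprintf("%.1f-%.1f", x$mortality_min, x$mortality_max))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
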