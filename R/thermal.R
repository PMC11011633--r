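#' Ice-bath probe calibration
#'
#' A probe immersed in a stirred ice bath should read 0 degC; the
#' calibration offset is the negative of its mean ice-bath reading, so
#' that `corrected = raw + offset` has ice-bath mean exactly zero.
#'
#' @param readings Data frame with columns `probe_id` and `reading_c`
#'   (at least 10 readings per probe).
#' @return Named numeric vector of offsets (degC) per probe.
#'
#' @examples
#' calibrate_probes(data.frame(probe_id = "f1", reading_c = rep(0.09, 12)))
#' @export
calibrate_probes <- function(readings) {
  if (!all(c("probe_id", "reading_c") %in% names(readings))) {
    stop("readings must have probe_id and reading_c columns", call. = FALSE)
  }
  if (nrow(readings) == 0) stop("empty calibration series", call. = FALSE)
  counts <- table(readings$probe_id)
  if (any(counts < 10)) {
    warning("probe(s) with fewer than 10 ice-bath readings: ",
            paste(names(counts)[counts < 10], collapse = ", "), call. = FALSE)
  }
  offs <- tapply(readings$reading_c, readings$probe_id, function(x) -mean(x))
  stats::setNames(as.numeric(offs), names(offs))
}

#' Apply calibration offsets to a temperature log
#'
#' @param log Temperature log data frame (`probe_id`, `probe_kind`,
#'   `timestamp`, `reading_c`).
#' @param offsets Named offsets from [calibrate_probes()]; probes with no
#'   offset are left unchanged.
#' @return The log with `reading_c` corrected.
#' @export
apply_calibration <- function(log, offsets) {
  o <- offsets[as.character(log$probe_id)]
  o[is.na(o)] <- 0
  log$reading_c <- log$reading_c + as.numeric(o)
  log
}

log_hours <- function(log) {
  ts <- log$timestamp
  if (inherits(ts, "POSIXt")) {
    as.numeric(difftime(ts, min(ts), units = "hours"))
  } else if (is.character(ts)) {
    tt <- as.POSIXct(ts, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    if (anyNA(tt)) tt <- as.POSIXct(ts, tz = "UTC")
    as.numeric(difftime(tt, min(tt), units = "hours"))
  } else {
    as.numeric(ts) - min(as.numeric(ts))
  }
}

#' Cool-down time of a fruit-probe set
#'
#' Elapsed hours from the first logged timestamp until fruit-core
#' temperatures first drop below the threshold. Two rules are offered:
#' `"majority"` declares cool-down when strictly more than half of the
#' fruit probes read below the threshold at one timestamp (the
#' large-scale-trial rule; 6 of 10 probes), and `"mean"` when the mean
#' of the fruit-probe readings drops below it. Resolution equals the
#' sampling interval.
#'
#' @param log Temperature log (`probe_id`, `probe_kind`, `timestamp`,
#'   `reading_c`); only `probe_kind == "fruit"` rows are used.
#' @param threshold Threshold in degC (default 3.5).
#' @param rule `"majority"` (default) or `"mean"`.
#' @return A list with `hours` (NA if never reached) and `reached`.
#' @export
cooldown_time <- function(log, threshold = 3.5, rule = c("majority", "mean")) {
  rule <- match.arg(rule)
  fr <- log[log$probe_kind == "fruit", , drop = FALSE]
  if (nrow(fr) == 0) stop("no fruit probes in log", call. = FALSE)
  hrs <- log_hours(log)[log$probe_kind == "fruit"]
  times <- sort(unique(hrs))
  nprobe <- length(unique(fr$probe_id))
  for (tt in times) {
    r <- fr$reading_c[hrs == tt]
    ok <- if (rule == "majority") sum(r < threshold) > nprobe / 2
          else mean(r) < threshold
    if (ok) return(list(hours = tt, reached = TRUE))
  }
  list(hours = NA_real_, reached = FALSE)
}

#' Constancy of the post-cool-down temperature profile
#'
#' Percentage of fruit-core readings after the cool-down period that lie
#' within `target +/- band` degC, both ends inclusive (a reading exactly
#' at the band edge counts as within).
#'
#' @inheritParams cooldown_time
#' @param target Target temperature (default 3.0 degC).
#' @param band Half-width of the acceptance band (default 0.5 degC).
#' @param after Cool-down end, in hours from the first timestamp.
#' @return Percentage in `[0, 100]`.
#' @export
constancy <- function(log, target = 3.0, band = 0.5, after = 0) {
  fr <- log$probe_kind == "fruit"
  hrs <- log_hours(log)
  sel <- fr & hrs >= after
  if (!any(sel)) stop("no post-cool-down fruit readings", call. = FALSE)
  r <- log$reading_c[sel]
  100 * mean(abs(r - target) <= band + 1e-9)
}

#' Temperature-profile summary of one treatment run
#'
#' One row with the profile QA fields: mean fruit-core temperature at
#' the first timestamp, overall mean over all probes, cool-down time,
#' post-cool-down fruit-core mean and standard deviation, and constancy
#' percentage. Fruit-core statistics use fruit probes only.
#'
#' @inheritParams cooldown_time
#' @param target,band Passed to [constancy()].
#' @return A one-row data frame (`start_mean`, `overall_mean`,
#'   `cooldown_hours`, `cooldown_reached`, `post_cooldown_mean`,
#'   `post_cooldown_sd`, `constancy_pct`).
#' @export
profile_summary <- function(log, threshold = 3.5, rule = c("majority", "mean"),
                            target = 3.0, band = 0.5) {
  rule <- match.arg(rule)
  hrs <- log_hours(log)
  fr <- log$probe_kind == "fruit"
  if (!any(fr)) stop("no fruit probes in log", call. = FALSE)
  start_mean <- mean(log$reading_c[fr & hrs == min(hrs)])
  overall_mean <- mean(log$reading_c)
  cd <- cooldown_time(log, threshold, rule)
  after <- if (cd$reached) cd$hours else max(hrs) + 1
  if (cd$reached) {
    post <- log$reading_c[fr & hrs >= after]
    data.frame(start_mean = start_mean, overall_mean = overall_mean,
               cooldown_hours = cd$hours, cooldown_reached = TRUE,
               post_cooldown_mean = mean(post),
               post_cooldown_sd = stats::sd(post),
               constancy_pct = constancy(log, target, band, after))
  } else {
    data.frame(start_mean = start_mean, overall_mean = overall_mean,
               cooldown_hours = NA_real_, cooldown_reached = FALSE,
               post_cooldown_mean = NA_real_, post_cooldown_sd = NA_real_,
               constancy_pct = NA_real_)
  }
}

#' Read a temperature log from delimited text
#'
#' Expects columns `probe_id`, `probe_kind` (`air`/`fruit`), `timestamp`
#' (ISO-8601 or numeric hours), `reading_c`.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_temperature_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "probe_kind", "timestamp", "reading_c")
  miss <- setdiff(need, names(log))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  log
}
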