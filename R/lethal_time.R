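#' Lethal-time point estimate
#'
#' Inverts the fitted mean model for one life stage at mortality level
#' `p`: `LT_p = (link(p) - alpha_stage) / beta_stage`. At `p = 0.999968`
#' this is the probit-9 quarantine-security lethal time.
#'
#' @param fit A converged [fit_time_mortality()] object.
#' @param stage Life-stage label present in the fit.
#' @param p Target mortality probability in (0, 1), e.g. `probit9`.
#'
#' @return Lethal time in days.
#' @export
lt_point <- function(fit, stage, p) {
  stopifnot(inherits(fit, "tm_fit"))
  ab <- lt_coef(fit, stage)
  if (abs(ab["beta"]) < .Machine$double.eps^0.5) {
    stop("slope for stage '", stage, "' is zero; lethal time undefined", call. = FALSE)
  }
  unname((link_transform(p, fit$spec$link) - ab["alpha"]) / ab["beta"])
}

lt_coef <- function(fit, stage) {
  if (!stage %in% fit$stages) {
    stop("stage '", stage, "' not in fitted model", call. = FALSE)
  }
  c(alpha = unname(fit$coefficients[paste0("alpha.", stage)]),
    beta = unname(fit$coefficients[paste0("beta.", stage)]))
}

#' Fieller confidence interval for a lethal time
#'
#' Confidence limits for the ratio `(link(p) - alpha) / beta` by
#' Fieller's theorem, using the 2x2 covariance block of
#' `(alpha_stage, beta_stage)` from the inverse observed information.
#' With `g = z^2 var(beta) / beta^2`, a finite interval exists for
#' `g < 1`; otherwise the denominator is too imprecise and the interval
#' is unbounded or exclusive, which is reported with an explicit flag
#' rather than clipped to finite numbers.
#'
#' @inheritParams lt_point
#' @param level Two-sided confidence level (default 0.95).
#'
#' @return A list with `estimate`, `low`, `high`, `g`, `level`, and
#'   `case` (`"finite"`, `"unbounded"`, or `"exclusive"`). For the
#'   non-finite cases `low`/`high` are `-Inf`/`Inf`.
#' @export
fieller_ci <- function(fit, stage, p, level = 0.95) {
  stopifnot(inherits(fit, "tm_fit"))
  if (is.null(fit$vcov)) stop("fit has no covariance matrix", call. = FALSE)
  ab <- lt_coef(fit, stage)
  idx <- paste0(c("alpha.", "beta."), stage)
  V <- fit$vcov[idx, idx]
  q <- link_transform(p, fit$spec$link)
  a <- q - ab["alpha"]; b <- ab["beta"]
  va <- V[1, 1]; vb <- V[2, 2]; cab <- -V[1, 2]  # cov(q - alpha, beta)
  z <- stats::qnorm(1 - (1 - level) / 2)
  g <- z^2 * vb / b^2
  est <- unname(a / b)
  disc <- (a * b - z^2 * cab)^2 - (b^2 - z^2 * vb) * (a^2 - z^2 * va)
  # in the finite case (g < 1) the quadratic always has real roots;
  # clamp roundoff-negative discriminants
  if (g < 1 && disc < 0) disc <- 0
  if (g < 1 && disc >= 0) {
    lim <- (unname(a * b - z^2 * cab) + c(-1, 1) * sqrt(disc)) / unname(b^2 - z^2 * vb)
    out <- list(estimate = est, low = lim[1], high = lim[2], g = unname(g),
                level = level, case = "finite")
  } else {
    out <- list(estimate = est, low = -Inf, high = Inf, g = unname(g),
                level = level,
                case = if (disc >= 0) "exclusive" else "unbounded")
  }
  out
}

#' Table of lethal-time estimates with Fieller intervals
#'
#' One row per stage and mortality level, ordered by stage then level,
#' consistent with [lt_point()] and [fieller_ci()].
#'
#' @inheritParams fieller_ci
#' @param stages Life stages to tabulate (default: all in the fit).
#' @param ps Mortality levels (default 50%, 95%, 99%, and probit 9).
#'
#' @return A data frame of class `lt_table` with columns `life_stage`,
#'   `p`, `lt_days`, `ci_low`, `ci_high`, `level`, `ci_case`.
#' @export
lt_table <- function(fit, stages = fit$stages,
                     ps = c(0.5, 0.95, 0.99, probit9), level = 0.95) {
  rows <- lapply(stages, function(s) {
    do.call(rbind, lapply(ps, function(p) {
      ci <- fieller_ci(fit, s, p, level)
      data.frame(life_stage = s, p = p, lt_days = ci$estimate,
                 ci_low = ci$low, ci_high = ci$high, level = level,
                 ci_case = ci$case, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lt_table", "data.frame")
  out
}

#' Write a lethal-time table in the wide report layout
#'
#' Stage rows, one column per mortality level, entries formatted as
#' `"estimate (low-high)"` in days, written as tab-separated text.
#'
#' @param x An [lt_table()] result.
#' @param path Output file path.
#' @param digits Digits after the decimal point (default 2).
#' @return The wide data frame, invisibly.
#' @export
write_lt_table <- function(x, path, digits = 2) {
  stopifnot(inherits(x, "lt_table"))
  fmt <- function(est, lo, hi) {
    ifelse(is.finite(lo) & is.finite(hi),
           sprintf("%.*f (%.*f-%.*f)", digits, est, digits, lo, digits, hi),
           sprintf("%.*f (unbounded)", digits, est))
  }
  ps <- sort(unique(x$p))
  wide <- data.frame(life_stage = unique(x$life_stage), stringsAsFactors = FALSE)
  for (p in ps) {
    sub <- x[x$p == p, ]
    col <- fmt(sub$lt_days, sub$ci_low, sub$ci_high)[match(wide$life_stage, sub$life_stage)]
    wide[[sprintf("LT_%s", format(100 * p))]] <- col
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(wide)
}

#' Serialize or restore a fitted model as JSON
#'
#' Stores coefficients, the covariance matrix (row-major), log-likelihood
#' and the model specification as structured text, so that lethal-time
#' tables can be regenerated without refitting.
#'
#' @param fit A `tm_fit`.
#' @param path JSON file path.
#' @return `write_fit()` returns `path` invisibly; `read_fit()` a
#'   `tm_fit` (without the original data payload).
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "tm_fit"))
  obj <- list(spec = unclass(fit$spec), stages = fit$stages,
              coefficients = as.list(fit$coefficients),
              covariance = as.vector(t(fit$vcov)),
              covariance_names = rownames(fit$vcov),
              loglik = fit$loglik, aic = fit$aic,
              converged = fit$converged, boundary = fit$boundary,
              n_obs = fit$n_obs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- obj$spec; class(spec) <- "tm_spec"
  k <- length(obj$covariance_names)
  vc <- matrix(obj$covariance, nrow = k, byrow = TRUE,
               dimnames = list(obj$covariance_names, obj$covariance_names))
  fit <- list(spec = spec, stages = obj$stages,
              coefficients = unlist(obj$coefficients),
              vcov = vc, vcov_ok = TRUE,
              loglik = obj$loglik, aic = obj$aic,
              converged = obj$converged, boundary = obj$boundary,
              separation = NULL, n_obs = obj$n_obs,
              data = NULL, dead = NULL, total = NULL)
  class(fit) <- "tm_fit"
  fit
}
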