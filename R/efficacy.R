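#' Treated-number extrapolation from control counts
#'
#' Estimates how many insects were treated in a large-scale trial by
#' scaling an interval for the mean control yield by the ratio of
#' treated to control fruit numbers. The default (`"two_sided_t"`)
#' computes `(mu +/- t_{1-(1-level)/2, r-1} * s / sqrt(r)) * n_l / n_c`,
#' where `mu` and `s` are the mean and standard deviation of the
#' per-replicate control counts and `r` their number.
#' `"one_sided_t_wearing"` returns the lower limit of a one-sided
#' interval at the same level, scaled; `"ippc_sd"` substitutes the
#' standard deviation for the standard error (one-sided; an approximate
#' rendering of the plant-protection-convention recommendation, whose
#' exact constant is not fixed here).
#'
#' @param control_counts Per-replicate pupae totals from control fruit
#'   (length >= 2).
#' @param n_control_fruit Number of fruit per control replicate.
#' @param n_treated_fruit Number of treated fruit the estimate is scaled
#'   to (e.g. per replicate, or the whole trial).
#' @param method One of `"two_sided_t"`, `"one_sided_t_wearing"`,
#'   `"ippc_sd"`.
#' @param level Confidence level (default 0.95).
#'
#' @return A list with `method`, `mean`, `se`, `scale` (`n_l/n_c`),
#'   `low`, `high` (unrounded scaled bounds; `high = Inf` for one-sided
#'   methods), and `low_int`, `high_int` rounded half-away-from-zero.
#'
#' @examples
#' treated_interval(c(10226, 10598, 10625), 200, 10200)
#' @export
treated_interval <- function(control_counts, n_control_fruit, n_treated_fruit,
                             method = c("two_sided_t", "one_sided_t_wearing", "ippc_sd"),
                             level = 0.95) {
  method <- match.arg(method)
  r <- length(control_counts)
  if (r < 2) stop("at least 2 control replicates are required", call. = FALSE)
  if (any(control_counts < 0)) stop("control counts must be non-negative", call. = FALSE)
  if (n_control_fruit <= 0 || n_treated_fruit <= 0) {
    stop("fruit counts must be positive", call. = FALSE)
  }
  mu <- mean(control_counts)
  s <- stats::sd(control_counts)
  se <- s / sqrt(r)
  scale <- n_treated_fruit / n_control_fruit
  if (method == "two_sided_t") {
    tq <- stats::qt(1 - (1 - level) / 2, r - 1)
    lo <- (mu - tq * se) * scale
    hi <- (mu + tq * se) * scale
  } else if (method == "one_sided_t_wearing") {
    tq <- stats::qt(level, r - 1)
    lo <- (mu - tq * se) * scale
    hi <- Inf
  } else {
    tq <- stats::qt(level, r - 1)
    lo <- (mu - tq * s) * scale
    hi <- Inf
  }
  list(method = method, mean = mu, se = se, scale = scale,
       low = lo, high = hi,
       low_int = round_half_away(lo),
       high_int = if (is.finite(hi)) round_half_away(hi) else Inf)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Confidence interval for a per-fruit yield
#'
#' `mean +/- q * se`, with `q` the Student-t quantile on `n - 1` degrees
#' of freedom (`method = "t"`) or the standard-normal quantile
#' (`method = "normal"`).
#'
#' @param mean Sample mean (e.g. pupae per fruit).
#' @param se Standard error of the mean (>= 0).
#' @param n Sample size (needed for `"t"`; `n >= 2`).
#' @param method `"t"` or `"normal"`.
#' @param level Confidence level (default 0.95).
#' @return `c(low, high)`.
#'
#' @examples
#' per_fruit_interval(51, 0.987, 30, "t")       # ~ (48.98, 53.02)
#' per_fruit_interval(77.1, 1.53, method = "normal")
#' @export
per_fruit_interval <- function(mean, se, n = NULL, method = c("t", "normal"),
                               level = 0.95) {
  method <- match.arg(method)
  if (se < 0) stop("`se` must be non-negative", call. = FALSE)
  if (method == "t") {
    if (is.null(n) || n < 2) stop("`n` >= 2 is required for the t interval", call. = FALSE)
    q <- stats::qt(1 - (1 - level) / 2, n - 1)
  } else {
    q <- stats::qnorm(1 - (1 - level) / 2)
  }
  c(low = mean - q * se, high = mean + q * se)
}

#' Confidence that true mortality meets a target (zero-survivor bound)
#'
#' The Couey-Chew confidence that the true mortality of a treatment is
#' at least `m`, given that `survivors` insects survived among `n`
#' treated: `C = 1 - sum_{i=0}^{s} choose(n, i) (1-m)^i m^(n-i)`, the
#' upper binomial tail evaluated in log space so that `n` of order 1e5
#' to 1e6 is exact. For zero survivors this reduces to `C = 1 - m^n`.
#'
#' @param n Number treated (>= 0).
#' @param survivors Number of survivors, `0 <= survivors <= n`.
#' @param m Target mortality in (0, 1), e.g. `probit9`.
#' @return Confidence in `[0, 1]`.
#'
#' @examples
#' mortality_confidence(499604, 0, probit9)   # > 0.99
#' @export
mortality_confidence <- function(n, survivors = 0, m = probit9) {
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  if (survivors < 0 || survivors > n) {
    stop("`survivors` must satisfy 0 <= survivors <= n", call. = FALSE)
  }
  if (m <= 0 || m >= 1) stop("`m` must lie in (0, 1)", call. = FALSE)
  if (n == 0) return(0)
  # survivors ~ Binomial(n, 1 - m) under mortality exactly m; the upper
  # tail is evaluated directly so that near-zero confidences keep full
  # precision
  stats::pbinom(survivors, n, 1 - m, lower.tail = FALSE)
}

#' Smallest trial size giving a target confidence with zero survivors
#'
#' Inverse of [mortality_confidence()] for trial design: the smallest
#' `n` such that observing zero survivors among `n` treated insects
#' demonstrates mortality `>= m` with at least the requested confidence,
#' `ceil(log(1 - confidence) / log(m))` with an exact integer check at
#' the boundary.
#'
#' @param m Target mortality in (0, 1).
#' @param confidence Required confidence in (0, 1).
#' @return Integer `n`.
#'
#' @examples
#' required_n(0.9, 0.95)   # 29
#' @export
required_n <- function(m, confidence) {
  if (m <= 0 || m >= 1) stop("`m` must lie in (0, 1)", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) {
    stop("`confidence` must lie in (0, 1)", call. = FALSE)
  }
  n <- max(1, ceiling(log1p(-confidence) / log(m)))
  while (n > 1 && mortality_confidence(n - 1, 0, m) >= confidence) n <- n - 1
  while (mortality_confidence(n, 0, m) < confidence) n <- n + 1
  as.integer(n)
}

#' Assemble a large-scale-trial efficacy report
#'
#' Runs all three treated-number extrapolation variants on the control
#' counts, applies the configured policy to pick the number treated
#' (default: the minimum across available estimates, the conservative
#' choice), and evaluates the confidence that true mortality meets the
#' target given the observed survivor count.
#'
#' @inheritParams treated_interval
#' @param survivors Survivors observed in the treated lots (default 0).
#' @param target_mortality Target mortality (default `probit9`).
#' @param extra_estimates Optional named numeric vector of additional
#'   treated-number estimates (e.g. from ancillary per-fruit yields or
#'   dissections) to include in the policy.
#' @param policy `"min"` (default) or `"max"` over the candidate
#'   treated-number estimates.
#' @param path Optional path; when given the report is also written as
#'   JSON.
#'
#' @return A list with the three estimator variants, the candidate
#'   estimates, the chosen `n_treated`, `confidence`, and a plain-text
#'   probit-9 style statement.
#' @export
efficacy_report <- function(control_counts, n_control_fruit, n_treated_fruit,
                            survivors = 0, target_mortality = probit9,
                            extra_estimates = NULL, policy = c("min", "max"),
                            level = 0.95, path = NULL) {
  policy <- match.arg(policy)
  variants <- lapply(c("two_sided_t", "one_sided_t_wearing", "ippc_sd"),
                     function(mth) treated_interval(control_counts, n_control_fruit,
                                                    n_treated_fruit, mth, level))
  names(variants) <- vapply(variants, `[[`, character(1), "method")
  cand <- c(control_two_sided_t = variants$two_sided_t$low_int,
            control_one_sided_t_wearing = variants$one_sided_t_wearing$low_int,
            control_ippc_sd = variants$ippc_sd$low_int)
  if (!is.null(extra_estimates)) cand <- c(cand, extra_estimates)
  n_treated <- if (policy == "min") min(cand) else max(cand)
  conf <- mortality_confidence(n_treated, survivors, target_mortality)
  statement <- sprintf(
    paste0("With %d survivors among an estimated %d treated insects, the data ",
           "support mortality of at least %s%% with %.4f%% confidence."),
    survivors, n_treated, format(100 * target_mortality), 100 * conf)
  out <- list(variants = variants, candidates = as.list(cand),
              policy = policy, n_treated = n_treated, survivors = survivors,
              target_mortality = target_mortality, confidence = conf,
              statement = statement)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  }
  out
}
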