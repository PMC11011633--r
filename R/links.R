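#' Mortality link functions
#'
#' Transform a mortality probability to the linear-predictor scale of a
#' quantal-response model, or back. Two links are supported: `"probit"`
#' (standard-normal quantile, the classical probit metameter) and
#' `"logit"` (log-odds).
#'
#' @param p Probability (or vector of probabilities) strictly inside (0, 1).
#' @param link One of `"probit"` or `"logit"`.
#' @param x Real value (or vector) on the link scale.
#'
#' @return `link_transform()` returns the link-scale value(s);
#'   `link_inverse()` returns probabilities in (0, 1).
#'
#' @examples
#' link_transform(0.5, "probit")          # 0
#' link_transform(probit9, "probit")      # ~ 3.9998, the "probit 9" deviate
#' link_inverse(link_transform(0.97, "logit"), "logit")
#' @export
link_transform <- function(p, link = c("probit", "logit")) {
  link <- match.arg(link)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  switch(link, probit = stats::qnorm(p), logit = stats::qlogis(p))
}

#' @rdname link_transform
#' @export
link_inverse <- function(x, link = c("probit", "logit")) {
  link <- match.arg(link)
  switch(link, probit = stats::pnorm(x), logit = stats::plogis(x))
}

#' The probit-9 quarantine security mortality level
#'
#' The mortality standard historically required of quarantine
#' disinfestation treatments: 99.9968% mortality (a survival rate of
#' 3.2e-5), i.e. probit value 9 on the 5-centred probit scale, a normal
#' deviate of about 4. Stored at full precision as the constant 0.999968.
#'
#' @format A length-one numeric.
#' @export
probit9 <- 0.999968
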