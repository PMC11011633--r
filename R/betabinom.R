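#' Beta-binomial distribution
#'
#' Density and random generation for the beta-binomial distribution
#' parameterised by the mean success probability `mu` and the intraclass
#' correlation `rho` in `[0, 1)`. With `a = mu (1 - rho) / rho` and
#' `b = (1 - mu)(1 - rho) / rho`, the count is binomial conditional on a
#' `Beta(a, b)` success probability. `rho = 0` is the binomial limit.
#' This is the observation model used for box-level survival counts,
#' where `rho` captures extra-binomial (between-box) variance.
#'
#' @param x Number of successes (vectorised).
#' @param size Number of trials (vectorised).
#' @param mu Mean success probability in (0, 1).
#' @param rho Overdispersion (intraclass correlation) in `[0, 1)`.
#' @param log Return log density?
#' @param n Number of random draws.
#'
#' @return `dbetabinom()` the (log) probability mass; `rbetabinom()`
#'   integer draws.
#'
#' @examples
#' sum(dbetabinom(0:12, 12, 0.3, 0.2))   # 1
#' dbetabinom(3, 10, 0.5, 0)             # equals dbinom(3, 10, 0.5)
#' @export
dbetabinom <- function(x, size, mu, rho, log = FALSE) {
  n <- max(length(x), length(size), length(mu), length(rho))
  x <- rep_len(x, n); size <- rep_len(size, n)
  mu <- rep_len(mu, n); rho <- rep_len(rho, n)
  if (any(x < 0 | x > size)) stop("`x` must satisfy 0 <= x <= size", call. = FALSE)
  if (any(size < 0)) stop("`size` must be non-negative", call. = FALSE)
  if (any(mu <= 0 | mu >= 1)) stop("`mu` must lie in (0, 1)", call. = FALSE)
  if (any(rho < 0 | rho >= 1)) stop("`rho` must lie in [0, 1)", call. = FALSE)
  out <- numeric(n)
  bin <- rho < 1e-8
  if (any(bin)) out[bin] <- stats::dbinom(x[bin], size[bin], mu[bin], log = TRUE)
  if (any(!bin)) {
    i <- !bin
    a <- mu[i] * (1 - rho[i]) / rho[i]
    b <- (1 - mu[i]) * (1 - rho[i]) / rho[i]
    out[i] <- lchoose(size[i], x[i]) + lbeta(x[i] + a, size[i] - x[i] + b) - lbeta(a, b)
  }
  if (log) out else exp(out)
}

#' @rdname dbetabinom
#' @export
rbetabinom <- function(n, size, mu, rho) {
  size <- rep_len(size, n); mu <- rep_len(mu, n); rho <- rep_len(rho, n)
  if (any(mu <= 0 | mu >= 1)) stop("`mu` must lie in (0, 1)", call. = FALSE)
  if (any(rho < 0 | rho >= 1)) stop("`rho` must lie in [0, 1)", call. = FALSE)
  p <- mu
  mix <- rho >= 1e-8
  if (any(mix)) {
    a <- mu[mix] * (1 - rho[mix]) / rho[mix]
    b <- (1 - mu[mix]) * (1 - rho[mix]) / rho[mix]
    p[mix] <- stats::rbeta(sum(mix), a, b)
  }
  stats::rbinom(n, size, p)
}

#' Beta-binomial log-likelihood of one observation
#'
#' Thin wrapper around [dbetabinom()] returning the log probability mass
#' of `k` dead among `n`, used as the building block of the
#' time-mortality model likelihood.
#'
#' @param k Observed count (e.g. dead insects).
#' @param n Number of trials; `n >= 1`.
#' @param mu Mean probability in (0, 1).
#' @param rho Overdispersion in `[0, 1)`.
#' @export
betabinom_loglik <- function(k, n, mu, rho) {
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  dbetabinom(k, n, mu, rho, log = TRUE)
}
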