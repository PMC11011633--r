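# Independent oracles used across tests. These are deliberately naive
# implementations (summation, root-finding, Monte Carlo) kept separate
# from the package's own code paths.

# standard-normal quantile by root-finding on pnorm
oracle_probit <- function(p) {
  stats::uniroot(function(x) stats::pnorm(x) - p, c(-10, 10), tol = 1e-13)$root
}

# binomial upper-tail confidence by explicit log-space summation
oracle_confidence <- function(n, s, m) {
  if (n == 0) return(0)
  i <- 0:s
  1 - sum(exp(lchoose(n, i) + i * log1p(-m) + (n - i) * log(m)))
}

# brute-force smallest n with zero-survivor confidence >= C
oracle_required_n <- function(m, conf, start = 1) {
  n <- start
  while (oracle_confidence(n, 0, m) < conf) n <- n + 1
  n
}

# simulate a single-stage binomial/beta-binomial bioassay with known
# coefficients on a chosen link
sim_stage_data <- function(seed, n_box = 50, size = 100, alpha = -2, beta = 0.5,
                           rho = 0, link = "probit",
                           durations = c(0, 2, 4, 6, 8)) {
  set.seed(seed)
  t <- rep(durations, length.out = n_box)
  mu <- link_inverse(alpha + beta * t, link)
  dead <- rbetabinom(n_box, size, pmin(pmax(mu, 1e-12), 1 - 1e-12), rho)
  data.frame(life_stage = "L3", duration_days = t, dead = dead, total = size)
}

# construct a tm_fit by hand from coefficients and a covariance matrix
hand_fit <- function(alpha, beta, V, link = "probit", stage = "L3") {
  nm <- c(paste0("alpha.", stage), paste0("beta.", stage))
  dimnames(V) <- list(nm, nm)
  structure(list(spec = bb_model_spec(link = link),
                 stages = stage,
                 coefficients = stats::setNames(c(alpha, beta), nm),
                 vcov = V, vcov_ok = TRUE, loglik = 0, aic = 0,
                 converged = TRUE, boundary = FALSE,
                 separation = stats::setNames(FALSE, stage), n_obs = 0,
                 data = NULL, dead = NULL, total = NULL),
            class = "tm_fit")
}
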