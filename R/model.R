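#' Specify a beta-binomial time-mortality model
#'
#' The model describes the probability that an insect in a treated box is
#' dead after `t` days of cold treatment as
#' `link(p) = alpha_stage + beta_stage * t`, with a beta-binomial
#' observation model whose overdispersion follows its own submodel
#' `rho = plogis(d_stage + e * t)` (per-stage intercepts with a single
#' shared time slope by default; per-stage slopes optionally). Replicate
#' structure can be absorbed by Gaussian random intercepts on the link
#' scale.
#'
#' @param link `"probit"`, `"logit"`, or `"auto"` (choose by smaller AIC).
#' @param dispersion `"betabinomial"` (default) or `"binomial"` (forces
#'   `rho = 0`; useful for diagnosing overdispersion).
#' @param disp_time_slope Include the shared time slope `e` in the
#'   dispersion submodel?
#' @param disp_stage_slopes Use stage-specific time slopes in the
#'   dispersion submodel instead of a single shared one?
#' @param random Random-intercept structure: `"none"`, `"replicate"`, or
#'   `"replicate_cultivar"` (one intercept per replicate-by-cultivar cell).
#' @param quadrature Integration for random intercepts: `"laplace"` with
#'   a 9-point adaptive Gauss-Hermite fallback (`"agq"`) when the
#'   Laplace curvature is ill-conditioned, or force `"agq"`.
#'
#' @return An object of class `tm_spec`.
#' @seealso [fit_time_mortality()]
#' @export
bb_model_spec <- function(link = c("auto", "logit", "probit"),
                          dispersion = c("betabinomial", "binomial"),
                          disp_time_slope = TRUE,
                          disp_stage_slopes = FALSE,
                          random = c("none", "replicate", "replicate_cultivar"),
                          quadrature = c("laplace", "agq")) {
  spec <- list(link = match.arg(link),
               dispersion = match.arg(dispersion),
               disp_time_slope = isTRUE(disp_time_slope),
               disp_stage_slopes = isTRUE(disp_stage_slopes),
               random = match.arg(random),
               quadrature = match.arg(quadrature))
  if (spec$disp_stage_slopes) spec$disp_time_slope <- TRUE
  class(spec) <- "tm_spec"
  spec
}

# Derive (dead, total) responses from a bioassay data frame. Accepts
# either explicit dead/total columns or pupae_count + treated_estimate,
# in which case dead = round(E - P) clipped at 0 and total = round(E).
tm_response <- function(data) {
  if (all(c("dead", "total") %in% names(data))) {
    dead <- as.numeric(data$dead); total <- as.numeric(data$total)
  } else if (all(c("pupae_count", "treated_estimate") %in% names(data))) {
    if (any(data$treated_estimate <= 0)) {
      stop("`treated_estimate` must be positive", call. = FALSE)
    }
    total <- round(as.numeric(data$treated_estimate))
    dead <- pmax(round(as.numeric(data$treated_estimate) - as.numeric(data$pupae_count)), 0)
    dead <- pmin(dead, total)
  } else {
    stop("data must contain either dead/total or pupae_count/treated_estimate columns",
         call. = FALSE)
  }
  if (any(total < 1)) stop("all group totals must be >= 1", call. = FALSE)
  list(dead = dead, total = total)
}

tm_stages <- function(data) {
  if (is.factor(data$life_stage)) {
    lv <- levels(data$life_stage)
  } else {
    lv <- unique(as.character(data$life_stage))
  }
  counts <- table(factor(as.character(data$life_stage), levels = lv))
  if (any(counts == 0)) {
    stop("life stage(s) with no observations: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  lv
}

# Parameter bookkeeping: names and starting values.
tm_parinfo <- function(data, spec, stages) {
  nm <- c(paste0("alpha.", stages), paste0("beta.", stages))
  if (spec$dispersion == "betabinomial") {
    nm <- c(nm, paste0("disp.", stages))
    if (spec$disp_stage_slopes) {
      nm <- c(nm, paste0("disp.t.", stages))
    } else if (spec$disp_time_slope) {
      nm <- c(nm, "disp.t")
    }
  }
  if (spec$random != "none") nm <- c(nm, "log_sigma_u")
  nm
}

tm_start <- function(data, spec, stages, resp) {
  linkfun <- function(p) link_transform(p, spec$link)
  start <- numeric(0)
  st <- as.character(data$life_stage)
  alpha <- beta <- numeric(length(stages))
  for (i in seq_along(stages)) {
    sel <- st == stages[i]
    # empirical-link regression on adjusted proportions, robust to 0/100% boxes
    padj <- (resp$dead[sel] + 0.5) / (resp$total[sel] + 1)
    y <- linkfun(padj)
    t <- data$duration_days[sel]
    if (length(unique(t)) < 2) {
      stop("stage '", stages[i], "' has fewer than 2 distinct durations; ",
           "the time slope is unidentifiable", call. = FALSE)
    }
    cf <- stats::coef(stats::lm(y ~ t))
    alpha[i] <- cf[1]; beta[i] <- cf[2]
  }
  start <- c(alpha, beta)
  if (spec$dispersion == "betabinomial") {
    start <- c(start, rep(stats::qlogis(0.05), length(stages)))
    if (spec$disp_stage_slopes) start <- c(start, rep(0, length(stages)))
    else if (spec$disp_time_slope) start <- c(start, 0)
  }
  if (spec$random != "none") start <- c(start, log(0.3))
  start
}

# Per-observation log-likelihood for given fixed parameters; `shift` is
# an optional additive offset on the link scale (random intercepts).
tm_obs_loglik <- function(par, data, spec, stages, resp, rows = NULL, shift = 0) {
  if (is.null(rows)) rows <- seq_len(nrow(data))
  st <- match(as.character(data$life_stage[rows]), stages)
  t <- data$duration_days[rows]
  k <- length(stages)
  eta <- par[st] + par[k + st] * t + shift
  mu <- link_inverse(eta, spec$link)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  if (spec$dispersion == "betabinomial") {
    deta <- par[2 * k + st]
    if (spec$disp_stage_slopes) deta <- deta + par[3 * k + st] * t
    else if (spec$disp_time_slope) deta <- deta + par[3 * k + 1] * t
    rho <- stats::plogis(deta)
    rho <- pmin(rho, 1 - 1e-10)
  } else {
    rho <- 0
  }
  dbetabinom(resp$dead[rows], resp$total[rows], mu, rho, log = TRUE)
}

# 9-point Gauss-Hermite nodes/weights for weight function exp(-x^2).
gh9 <- list(
  nodes = c(-3.19099320178152704, -2.26658058453184311, -1.46855328921666793,
            -0.72355101875283757, 0,
            0.72355101875283757, 1.46855328921666793,
            2.26658058453184311, 3.19099320178152704),
  weights = c(3.96069772632644249e-05, 4.94362427553694711e-03,
              8.84745273943765715e-02, 4.32651559002555750e-01,
              7.20235215606050957e-01, 4.32651559002555750e-01,
              8.84745273943765715e-02, 4.94362427553694711e-03,
              3.96069772632644249e-05))

# Log marginal likelihood contribution of one cluster, integrating a
# Gaussian random intercept by Laplace approximation (adaptive 9-point
# Gauss-Hermite when the curvature at the mode is ill-conditioned).
tm_cluster_loglik <- function(par, data, spec, stages, resp, rows, sigma, quadrature) {
  f <- function(u) {
    sum(tm_obs_loglik(par, data, spec, stages, resp, rows, shift = u)) -
      u^2 / (2 * sigma^2)
  }
  opt <- stats::optimize(f, interval = c(-1, 1) * (5 * sigma + 2), maximum = TRUE)
  uhat <- opt$maximum
  h <- 1e-4 * max(1, abs(uhat))
  hess <- -(f(uhat + h) - 2 * opt$objective + f(uhat - h)) / h^2
  ill <- !is.finite(hess) || hess <= 1 / (100 * sigma^2)
  if (quadrature == "laplace" && !ill) {
    return(opt$objective - 0.5 * log(sigma^2 * hess))
  }
  # adaptive Gauss-Hermite around the mode
  s <- if (is.finite(hess) && hess > 0) 1 / sqrt(hess) else sigma
  u <- uhat + sqrt(2) * s * gh9$nodes
  lg <- vapply(u, f, numeric(1)) + gh9$nodes^2 + log(gh9$weights)
  m <- max(lg)
  m + log(sum(exp(lg - m))) + 0.5 * log(2 * s^2 / sigma^2)
}

tm_nll <- function(par, data, spec, stages, resp, clusters = NULL) {
  if (is.null(clusters)) {
    ll <- sum(tm_obs_loglik(par, data, spec, stages, resp))
  } else {
    sigma <- exp(par[length(par)])
    fpar <- par[-length(par)]
    if (sigma < 1e-4) {
      ll <- sum(tm_obs_loglik(fpar, data, spec, stages, resp))
    } else {
      ll <- sum(vapply(clusters, function(rows) {
        tm_cluster_loglik(fpar, data, spec, stages, resp, rows, sigma,
                          spec$quadrature)
      }, numeric(1)))
    }
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit a beta-binomial time-mortality model by maximum likelihood
#'
#' Fits the model described in [bb_model_spec()] to box-level (or
#' duration-level) bioassay records. The negative log-likelihood is
#' minimised by quasi-Newton (BFGS) iteration from empirical-link
#' starting values; random intercepts, if requested, are integrated out
#' by a Laplace approximation with an adaptive 9-point Gauss-Hermite
#' fallback. The covariance of the estimates is the inverse observed
#' information at the optimum.
#'
#' @param data A data frame with columns `life_stage`, `duration_days`,
#'   and either `dead`/`total` or `pupae_count`/`treated_estimate` (in
#'   the latter case `dead = round(E - P)` clipped at zero and
#'   `total = round(E)`). Random-effect structures additionally require
#'   `replicate` (and `cultivar`).
#' @param spec A [bb_model_spec()].
#' @param start Optional numeric vector of starting values.
#' @param control Passed to [stats::optim()] (sensible defaults set).
#'
#' @return An object of class `tm_fit`: a list with elements `spec`,
#'   `stages`, `coefficients`, `vcov` (inverse observed information,
#'   full parameter block), `loglik`, `aic`, `converged`, `boundary`
#'   (random-effect variance pinned at zero), `separation` (complete
#'   separation suspected for some stage), `n_obs`, and the prepared
#'   response (`data`, `dead`, `total`) for downstream diagnostics.
#'
#' @examples
#' tot <- cold_tolerance_totals("Hayward", "L3")
#' fit <- fit_time_mortality(tot, bb_model_spec(link = "logit"))
#' lt_point(fit, "L3", probit9)
#' @export
fit_time_mortality <- function(data, spec = bb_model_spec(), start = NULL,
                               control = list()) {
  stopifnot(inherits(spec, "tm_spec"))
  if (!all(c("life_stage", "duration_days") %in% names(data))) {
    stop("data must contain life_stage and duration_days columns", call. = FALSE)
  }
  if (spec$link == "auto") {
    cand <- lapply(c("logit", "probit"), function(lk) {
      s <- spec; s$link <- lk
      fit_time_mortality(data, s, start = NULL, control = control)
    })
    aics <- vapply(cand, function(f) f$aic, numeric(1))
    best <- cand[[which.min(aics)]]
    best$link_selection <- data.frame(link = c("logit", "probit"), aic = aics)
    return(best)
  }
  data <- as.data.frame(data)
  resp <- tm_response(data)
  stages <- tm_stages(data)
  clusters <- NULL
  if (spec$random != "none") {
    if (!"replicate" %in% names(data)) {
      stop("random-intercept models require a `replicate` column", call. = FALSE)
    }
    grp <- if (spec$random == "replicate") as.character(data$replicate)
           else paste(data$replicate, data$cultivar, sep = ":")
    if (length(unique(grp)) < 2) {
      stop("random-intercept models require >= 2 replicate levels", call. = FALSE)
    }
    clusters <- split(seq_len(nrow(data)), grp)
  }
  parnames <- tm_parinfo(data, spec, stages)
  if (is.null(start)) start <- tm_start(data, spec, stages, resp)
  stopifnot(length(start) == length(parnames))
  ctrl <- utils::modifyList(list(maxit = 1000, reltol = 1e-12), control)
  opt <- stats::optim(start, tm_nll, data = data, spec = spec, stages = stages,
                      resp = resp, clusters = clusters,
                      method = "BFGS", control = ctrl)
  # one restart from the optimum guards against premature BFGS stops
  opt2 <- stats::optim(opt$par, tm_nll, data = data, spec = spec, stages = stages,
                       resp = resp, clusters = clusters,
                       method = "BFGS", control = ctrl)
  if (opt2$value <= opt$value) opt <- opt2
  par <- stats::setNames(opt$par, parnames)
  hess <- try(stats::optimHess(opt$par, tm_nll, data = data, spec = spec,
                               stages = stages, resp = resp, clusters = clusters),
              silent = TRUE)
  vc <- NULL
  vcov_ok <- FALSE
  if (!inherits(hess, "try-error") && all(is.finite(hess))) {
    vc <- try(solve(hess), silent = TRUE)
    if (!inherits(vc, "try-error") && all(is.finite(vc)) &&
        all(diag(vc) > 0)) {
      vc <- (vc + t(vc)) / 2
      dimnames(vc) <- list(parnames, parnames)
      vcov_ok <- TRUE
    } else vc <- NULL
  }
  # complete-separation heuristic: a stage with no interior response and
  # an exploded slope cannot pin its coefficients
  st <- as.character(data$life_stage)
  sep <- vapply(seq_along(stages), function(i) {
    sel <- st == stages[i]
    interior <- any(resp$dead[sel] > 0 & resp$dead[sel] < resp$total[sel])
    big <- abs(par[length(stages) + i]) > 15
    !interior || big
  }, logical(1))
  boundary <- FALSE
  if (spec$random != "none") {
    boundary <- exp(par["log_sigma_u"]) < 1e-3
  }
  fit <- list(spec = spec, stages = stages,
              coefficients = par, vcov = vc, vcov_ok = vcov_ok,
              loglik = -opt$value,
              aic = 2 * length(par) + 2 * opt$value,
              converged = opt$convergence == 0 && is.finite(opt$value),
              boundary = boundary,
              separation = stats::setNames(sep, stages),
              n_obs = nrow(data),
              data = data, dead = resp$dead, total = resp$total)
  class(fit) <- "tm_fit"
  if (any(sep)) {
    warning("possible complete separation for stage(s): ",
            paste(stages[sep], collapse = ", "), call. = FALSE)
  }
  fit
}

#' @export
print.tm_fit <- function(x, ...) {
  cat("Beta-binomial time-mortality model (", x$spec$link, " link)\n", sep = "")
  cat("  observations:", x$n_obs, " stages:", paste(x$stages, collapse = ", "), "\n")
  cat("  logLik:", format(x$loglik, digits = 6), " AIC:", format(x$aic, digits = 6),
      " converged:", x$converged, "\n")
  if (x$boundary) cat("  note: random-effect variance pinned at zero\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.tm_fit <- function(object, ...) object$coefficients

#' @export
vcov.tm_fit <- function(object, ...) object$vcov

#' @export
logLik.tm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

# Fitted mean mortality and overdispersion per observation (fixed
# effects only, i.e. at the median replicate).
tm_fitted <- function(fit, data = fit$data) {
  par <- fit$coefficients; stages <- fit$stages; spec <- fit$spec
  k <- length(stages)
  st <- match(as.character(data$life_stage), stages)
  t <- data$duration_days
  mu <- link_inverse(par[st] + par[k + st] * t, spec$link)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  if (spec$dispersion == "betabinomial") {
    deta <- par[2 * k + st]
    if (spec$disp_stage_slopes) deta <- deta + par[3 * k + st] * t
    else if (spec$disp_time_slope) deta <- deta + par[3 * k + 1] * t
    rho <- pmin(stats::plogis(deta), 1 - 1e-10)
  } else rho <- rep(0, nrow(data))
  list(mu = mu, rho = rho)
}

#' Simulation-based overdispersion check
#'
#' Compares the variance of binomial-scale Pearson residuals in the data
#' with its distribution over datasets simulated from the fitted model,
#' in the spirit of simulation-based residual diagnostics for count
#' models. A fitted model that accounts for the dispersion in the data
#' yields an approximately uniform p-value; a binomial fit to
#' overdispersed data yields a dispersion statistic well above 1 and a
#' small p-value.
#'
#' @param fit A converged [fit_time_mortality()] object.
#' @param n_sim Number of simulated datasets (>= 100).
#' @param seed Integer seed; the check is deterministic given the seed
#'   and does not disturb the global RNG stream.
#' @param refit Refit the model to every simulated dataset before
#'   computing its residual statistic (the exact parametric-bootstrap
#'   test, with a p-value uniform under a correctly specified model) or
#'   keep the original fit for all of them (`FALSE`, much faster and
#'   slightly conservative).
#'
#' @return A list with `dispersion_statistic` (ratio of observed to mean
#'   simulated residual variance), `p_value`, `n_sim`, and `seed`.
#' @export
dispersion_check <- function(fit, n_sim = 200, seed = 1, refit = FALSE) {
  stopifnot(inherits(fit, "tm_fit"))
  if (!fit$converged) stop("dispersion_check requires a converged fit", call. = FALSE)
  if (n_sim < 100) stop("`n_sim` must be >= 100", call. = FALSE)
  fv <- tm_fitted(fit)
  # mean squared residual scaled by the model's own (beta-binomial)
  # variance: close to 1 under a well-specified model, which keeps the
  # statistic nearly pivotal
  scaled_msr <- function(dead, fitted) {
    v <- fit$total * fitted$mu * (1 - fitted$mu) *
      (1 + (fit$total - 1) * fitted$rho)
    mean((dead - fit$total * fitted$mu)^2 / v)
  }
  spec <- fit$spec; stages <- fit$stages
  sim_stat <- function(dead) {
    if (!refit) return(scaled_msr(dead, fv))
    resp <- list(dead = dead, total = fit$total)
    opt <- stats::optim(fit$coefficients, tm_nll, data = fit$data, spec = spec,
                        stages = stages, resp = resp, clusters = NULL,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10))
    refitted <- fit
    refitted$coefficients <- stats::setNames(opt$par, names(fit$coefficients))
    scaled_msr(dead, tm_fitted(refitted))
  }
  obs <- sim_stat(fit$dead)
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      sim_stat(rbetabinom(length(fit$total), fit$total, fv$mu, fv$rho))
    }, numeric(1))
  })
  stat <- obs / mean(sims)
  p <- (1 + sum(sims >= obs)) / (n_sim + 1)
  list(dispersion_statistic = stat, p_value = p, n_sim = n_sim, seed = seed)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
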