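test_that("binomial-data fit matches the IRLS oracle and recovers truth", {
  d <- sim_stage_data(1, n_box = 50, size = 100, alpha = -2, beta = 0.5,
                      rho = 0, link = "probit")
  fit <- fit_time_mortality(d, bb_model_spec(link = "probit",
                                             dispersion = "binomial"))
  expect_true(fit$converged)
  # independent iteratively-reweighted least-squares fit
  g <- glm(cbind(dead, total - dead) ~ duration_days, data = d,
           family = binomial(link = "probit"))
  expect_equal(unname(coef(fit)[c("alpha.L3", "beta.L3")]),
               unname(coef(g)), tolerance = 1e-4)
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit)["alpha.L3"] - (-2)), 3 * se["alpha.L3"])
  expect_lt(abs(coef(fit)["beta.L3"] - 0.5), 3 * se["beta.L3"])
})

test_that("returned optimum dominates the generating parameters (MLE property)", {
  for (s in 1:8) {
    d <- sim_stage_data(s, n_box = 40, size = 200, alpha = -2.5, beta = 0.6,
                        rho = 0.08, link = "logit")
    fit <- fit_time_mortality(d, bb_model_spec(link = "logit"))
    resp <- list(dead = d$dead, total = d$total)
    truth <- c(-2.5, 0.6, qlogis(0.08), 0)
    ll_true <- -coldtreat:::tm_nll(truth, d, fit$spec, "L3", resp)
    expect_gte(fit$loglik, ll_true - 1e-6)
  }
})

test_that("fitted mortality is monotone in duration for positive slopes", {
  d <- sim_stage_data(3, rho = 0.05, link = "logit")
  fit <- fit_time_mortality(d, bb_model_spec(link = "logit"))
  expect_gt(coef(fit)["beta.L3"], 0)
  grid <- data.frame(life_stage = "L3", duration_days = seq(0, 20, 0.5))
  mu <- coldtreat:::tm_fitted(fit, grid)$mu
  expect_true(all(diff(mu) >= 0))
})

test_that("duration-level beta-binomial optimum matches glmmTMB", {
  skip_if_not_installed("glmmTMB")
  tot <- cold_tolerance_totals("Hayward", "L3")
  fit <- fit_time_mortality(tot, bb_model_spec(link = "logit"))
  d <- tot
  d$dead <- pmax(round(d$treated_estimate - d$pupae_count), 0)
  d$tot <- round(d$treated_estimate)
  m <- glmmTMB::glmmTMB(cbind(dead, tot - dead) ~ duration_days,
                        dispformula = ~duration_days,
                        family = glmmTMB::betabinomial(link = "logit"), data = d)
  expect_equal(unname(coef(fit)[c("alpha.L3", "beta.L3")]),
               unname(glmmTMB::fixef(m)$cond), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(m)), tolerance = 1e-4)
})

test_that("degenerate designs are rejected, separation is flagged", {
  d1 <- data.frame(life_stage = "L3", duration_days = 5,
                   dead = c(3, 4), total = 10)
  expect_error(fit_time_mortality(d1, bb_model_spec(link = "logit")),
               "unidentifiable")
  d2 <- data.frame(life_stage = c("L3", "L3", "egg"),
                   duration_days = c(0, 5, 3), dead = c(1, 2, NA),
                   total = c(10, 10, 10))
  d2 <- d2[d2$life_stage == "L3", ]
  d2$life_stage <- factor(d2$life_stage, levels = c("L3", "egg"))
  expect_error(fit_time_mortality(d2, bb_model_spec(link = "logit")),
               "no observations")
  # all-alive then all-dead with no interior point: separation
  d3 <- data.frame(life_stage = "L3",
                   duration_days = rep(c(0, 2, 10, 12), each = 3),
                   dead = rep(c(0, 0, 50, 50), each = 3), total = 50)
  expect_warning(f3 <- fit_time_mortality(d3, bb_model_spec(link = "logit",
                                                            dispersion = "binomial")),
                 "separation")
  expect_true(any(f3$separation))
})

test_that("auto link selection picks the smaller AIC and records both", {
  tot <- cold_tolerance_totals("both", "L3")
  fit <- fit_time_mortality(tot, bb_model_spec(link = "auto"))
  expect_s3_class(fit, "tm_fit")
  expect_named(fit$link_selection, c("link", "aic"))
  expect_equal(fit$aic, min(fit$link_selection$aic))
})

test_that("random-intercept machinery reduces to the fixed fit at sigma = 0", {
  d <- gen_cold_tolerance("y2019", default_params(sigma_u = 0), seed = 11)
  d <- d[d$cultivar == "Hayward", ]
  ff <- fit_time_mortality(d, bb_model_spec(link = "logit"))
  # the marginal likelihood at vanishing sigma equals the fixed one
  spec_r <- bb_model_spec(link = "logit", random = "replicate")
  resp <- coldtreat:::tm_response(d)
  clus <- split(seq_len(nrow(d)), as.character(d$replicate))
  nll_fixed <- coldtreat:::tm_nll(coef(ff), d, ff$spec, "L3", resp)
  nll_rand0 <- coldtreat:::tm_nll(c(coef(ff), -20), d, spec_r, "L3", resp, clus)
  expect_equal(nll_fixed, nll_rand0, tolerance = 1e-6)
  fm <- fit_time_mortality(d, spec_r)
  expect_true(fm$converged)
  expect_lt(exp(coef(fm)["log_sigma_u"])^2, 0.01)
  expect_equal(unname(coef(fm)[c("alpha.L3", "beta.L3")]),
               unname(coef(ff)[c("alpha.L3", "beta.L3")]), tolerance = 0.05)
})

test_that("replicate-effect standard deviation is recovered", {
  p <- default_params(sigma_u = 0.5, cultivar_shift = 0)
  ok <- 0; runs <- 12
  for (s in 1:runs) {
    d <- gen_cold_tolerance("custom", p, seed = s,
                            durations = c(0, 3, 5, 8, 11), stages = "L3",
                            cultivars = "Hayward", n_rep = 8, boxes = 5,
                            fruit_per_box = 5)
    fm <- fit_time_mortality(d, bb_model_spec(link = "logit",
                                              random = "replicate"))
    sg <- exp(coef(fm)["log_sigma_u"])
    ok <- ok + (sg >= 0.2 && sg <= 0.9)
  }
  expect_gte(ok, ceiling(0.75 * runs))
})

test_that("dispersion p-values are uniform under a well-specified model", {
  n <- 100; pv <- numeric(n)
  for (s in 1:n) {
    d <- sim_stage_data(s, n_box = 40, size = 300, alpha = -3.16, beta = 0.78,
                        rho = 0.05, link = "logit",
                        durations = c(0, 4, 8, 12, 16))
    f <- fit_time_mortality(d, bb_model_spec(link = "logit"))
    pv[s] <- dispersion_check(f, n_sim = 119, seed = s, refit = TRUE)$p_value
  }
  # smear the lattice p-values over their cell before testing uniformity
  set.seed(7)
  pj <- pv - runif(n, 0, 1 / 120)
  expect_gt(ks.test(pj, "punif")$p.value, 0.01)
})

test_that("binomial fits to overdispersed data are flagged", {
  rej <- 0; runs <- 10
  for (s in 1:runs) {
    d <- sim_stage_data(s, n_box = 40, size = 300, alpha = -3.16, beta = 0.78,
                        rho = 0.3, link = "logit", durations = c(0, 4, 8, 12, 16))
    f <- fit_time_mortality(d, bb_model_spec(link = "logit",
                                             dispersion = "binomial"))
    dc <- dispersion_check(f, n_sim = 199, seed = s)
    expect_gt(dc$dispersion_statistic, 1)
    rej <- rej + (dc$p_value < 0.05)
  }
  expect_gte(rej, 8)
})

test_that("dispersion check is deterministic and leaves the RNG alone", {
  d <- sim_stage_data(5, rho = 0.1, link = "logit")
  f <- fit_time_mortality(d, bb_model_spec(link = "logit"))
  set.seed(123); before <- runif(1)
  a <- dispersion_check(f, n_sim = 150, seed = 9)
  b <- dispersion_check(f, n_sim = 150, seed = 9)
  expect_identical(a, b)
  set.seed(123)
  expect_identical(runif(1), before)
  expect_error(dispersion_check(f, n_sim = 50, seed = 1), ">= 100")
})
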