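test_that("lethal-time inversion matches hand-set coefficients", {
  V <- diag(c(1e-4, 1e-6))
  f <- hand_fit(alpha = 0, beta = 0.25, V = V, link = "probit")
  expect_equal(lt_point(f, "L3", 0.5), 0)
  expect_equal(lt_point(f, "L3", probit9), oracle_probit(probit9) / 0.25,
               tolerance = 1e-9)
  expect_equal(lt_point(f, "L3", probit9), 15.99022, tolerance = 1e-5)
  f2 <- hand_fit(alpha = -2, beta = 0.5, V = V, link = "probit")
  expect_equal(lt_point(f2, "L3", 0.5), 4)  # -alpha/beta at link(0.5) = 0
  ps <- c(0.5, 0.9, 0.99, probit9)
  lts <- vapply(ps, function(p) lt_point(f2, "L3", p), numeric(1))
  expect_true(all(diff(lts) > 0))
  f0 <- hand_fit(alpha = -2, beta = 0, V = V)
  expect_error(lt_point(f0, "L3", 0.5), "zero")
  expect_error(lt_point(f2, "egg", 0.5), "not in fitted model")
})

test_that("Fieller interval collapses to the point as covariance vanishes", {
  V <- matrix(c(0.04, -0.003, -0.003, 0.0009), 2)
  f <- hand_fit(alpha = -3, beta = 0.6, V = 1e-18 * V, link = "logit")
  ci <- fieller_ci(f, "L3", probit9)
  expect_equal(ci$low, ci$estimate, tolerance = 1e-6)
  expect_equal(ci$high, ci$estimate, tolerance = 1e-6)
  # width shrinks monotonically as the covariance is scaled down
  widths <- vapply(c(1, 0.5, 0.1, 0.01), function(sc) {
    ci <- fieller_ci(hand_fit(-3, 0.6, sc * V, link = "logit"), "L3", probit9)
    ci$high - ci$low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("Fieller endpoints agree with a parametric bootstrap of the ratio", {
  tot <- cold_tolerance_totals("Hayward", "L3")
  fit <- fit_time_mortality(tot, bb_model_spec(link = "logit"))
  ci <- fieller_ci(fit, "L3", probit9)
  expect_identical(ci$case, "finite")
  expect_true(ci$low <= ci$estimate && ci$estimate <= ci$high)
  idx <- c("alpha.L3", "beta.L3")
  V <- fit$vcov[idx, idx]
  set.seed(2024)
  z <- matrix(rnorm(2 * 10000), ncol = 2) %*% chol(V)
  a <- link_transform(probit9, "logit") - (coef(fit)["alpha.L3"] + z[, 1])
  b <- coef(fit)["beta.L3"] + z[, 2]
  qs <- quantile(a / b, c(0.025, 0.975))
  expect_equal(ci$low, unname(qs[1]), tolerance = 0.05)
  expect_equal(ci$high, unname(qs[2]), tolerance = 0.05)
})

test_that("imprecise slopes yield flagged unbounded intervals, never a finite lie", {
  V <- matrix(c(0.05, 0, 0, 0.25), 2)  # var(beta) >> beta^2 / z^2
  f <- hand_fit(alpha = -3, beta = 0.6, V = V, link = "logit")
  ci <- fieller_ci(f, "L3", probit9)
  expect_gte(ci$g, 1)
  expect_true(ci$case %in% c("unbounded", "exclusive"))
  expect_identical(ci$low, -Inf)
  expect_identical(ci$high, Inf)
})

test_that("lt_table rows are complete, ordered, and round-trip serialization", {
  tot <- cold_tolerance_totals("both")
  fit <- fit_time_mortality(tot, bb_model_spec(link = "logit"))
  tab <- lt_table(fit)
  expect_equal(nrow(tab), length(fit$stages) * 4)
  expect_equal(tab$life_stage, rep(fit$stages, each = 4))
  expect_true(all(tab$p == rep(c(0.5, 0.95, 0.99, probit9), length(fit$stages))))
  one <- tab[tab$life_stage == "L3" & tab$p == 0.5, ]
  expect_equal(one$lt_days, lt_point(fit, "L3", 0.5))
  # regenerating the table from a serialized fit changes nothing
  path <- tempfile(fileext = ".json")
  write_fit(fit, path)
  fit2 <- read_fit(path)
  tab2 <- lt_table(fit2)
  expect_equal(tab2$lt_days, tab$lt_days, tolerance = 1e-12)
  expect_equal(tab2$ci_low, tab$ci_low, tolerance = 1e-10)
  # wide writer emits one row per stage
  out <- tempfile(fileext = ".tsv")
  wide <- write_lt_table(tab, out)
  expect_equal(nrow(wide), length(fit$stages))
  expect_true(file.exists(out))
})

test_that("pooled refits reproduce the qualitative stage tolerance ordering", {
  tot <- cold_tolerance_totals("both")
  fit <- fit_time_mortality(tot, bb_model_spec(link = "logit"))
  lt <- vapply(c("L1", "L2", "egg", "L3"),
               function(s) lt_point(fit, s, probit9), numeric(1))
  # first instars most susceptible, third instars most tolerant
  expect_true(all(diff(lt) > 0))
})
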