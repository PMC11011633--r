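mklog <- function(hours, readings, probe = "f1", kind = "fruit") {
  data.frame(probe_id = probe, probe_kind = kind, timestamp = hours,
             reading_c = readings, stringsAsFactors = FALSE)
}

test_that("ice-bath calibration zeroes the corrected mean", {
  expect_equal(unname(calibrate_probes(
    data.frame(probe_id = "a", reading_c = rep(0, 12)))), 0)
  expect_equal(unname(calibrate_probes(
    data.frame(probe_id = "a", reading_c = rep(0.09, 12)))), -0.09)
  suppressWarnings(
    expect_equal(unname(calibrate_probes(
      data.frame(probe_id = "a", reading_c = c(0.1, 0.2)))), -0.15))
  ice <- data.frame(probe_id = rep(c("a", "b"), each = 60),
                    reading_c = rep(c(0.07, -0.11), each = 60) + 0.001)
  offs <- calibrate_probes(ice)
  corrected <- ice$reading_c + offs[ice$probe_id]
  expect_equal(abs(mean(corrected[ice$probe_id == "a"])), 0, tolerance = 1e-9)
  expect_error(calibrate_probes(data.frame(probe_id = character(0),
                                           reading_c = numeric(0))), "empty")
})

test_that("majority cool-down rule finds the sixth probe of ten", {
  hours <- 0:12
  logs <- do.call(rbind, lapply(1:10, function(i) {
    mklog(hours, ifelse(hours >= i - 1, 3.0, 4.0), sprintf("f%02d", i))
  }))
  cd <- cooldown_time(logs, 3.5, "majority")
  expect_true(cd$reached)
  expect_equal(cd$hours, 5)  # probes 1..6 below threshold from hour 5
  # already cold at loading
  cold <- mklog(0:5, rep(3.0, 6))
  expect_equal(cooldown_time(cold)$hours, 0)
  warm <- mklog(0:5, rep(10, 6))
  nr <- cooldown_time(warm)
  expect_false(nr$reached)
  expect_true(is.na(nr$hours))
})

test_that("cool-down time is monotone non-increasing in the threshold", {
  tl <- gen_temperature_log(seed = 4, noise_sd = 0.05, duration_h = 120)
  hrs <- vapply(c(3.2, 3.5, 4.0, 5.0), function(th) {
    cooldown_time(tl, th)$hours
  }, numeric(1))
  expect_true(all(diff(hrs) <= 0))
})

test_that("constancy counts band-inclusive fruit readings only", {
  expect_equal(constancy(mklog(0:9, rep(3, 10))), 100)
  expect_equal(constancy(mklog(0:9, rep(4, 10))), 0)
  expect_equal(constancy(mklog(0:9, rep(c(3, 4), 5))), 50)
  # readings exactly at 2.5 and 3.5 are inside the band
  expect_equal(constancy(mklog(0:3, c(2.5, 3.5, 2.5, 3.5))), 100)
  # permutation invariance over probes
  two <- rbind(mklog(0:9, rep(c(3, 4), 5), "f1"),
               mklog(0:9, rep(c(4, 3), 5), "f2"))
  expect_equal(constancy(two), constancy(two[rev(seq_len(nrow(two))), ]))
  # air probes are excluded from the denominator
  withair <- rbind(mklog(0:9, rep(3, 10), "f1"),
                   mklog(0:9, rep(9, 10), "a1", "air"))
  expect_equal(constancy(withair), 100)
  expect_error(constancy(mklog(0:9, rep(3, 10)), after = 100), "post-cool-down")
})

test_that("profile summary recovers the generating plateau and crossing", {
  tl <- gen_temperature_log(start_c = 25, plateau_c = 3.0, time_constant_h = 14,
                            noise_sd = 0, seed = 1, duration_h = 300)
  truth <- attr(tl, "truth")
  ps <- profile_summary(tl)
  expect_lte(abs(ps$cooldown_hours - truth$crossing_h), 0.5)
  expect_lt(abs(ps$post_cooldown_mean - 3.0), 0.05)
  expect_equal(ps$constancy_pct, 100)
  # deterministic given the seed
  a <- profile_summary(gen_temperature_log(seed = 9))
  b <- profile_summary(gen_temperature_log(seed = 9))
  expect_identical(a, b)
  # single constant-target probe: degenerate but well-defined
  const <- mklog(0:49, rep(3.0, 50))
  pc <- profile_summary(const)
  expect_equal(pc$cooldown_hours, 0)
  expect_equal(pc$constancy_pct, 100)
  expect_equal(pc$post_cooldown_sd, 0)
})

test_that("calibration absorbs a constant sensor bias end to end", {
  tl <- gen_temperature_log(seed = 6, noise_sd = 0.05, duration_h = 200)
  biased <- tl
  biased$reading_c <- biased$reading_c + 0.4
  ice <- data.frame(probe_id = rep(unique(tl$probe_id), each = 20),
                    reading_c = 0.4)
  fixed <- apply_calibration(biased, calibrate_probes(ice))
  expect_equal(profile_summary(fixed), profile_summary(tl), tolerance = 1e-12)
})
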