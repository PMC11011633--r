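#' Ground-truth parameters for the synthetic-data generator
#'
#' Defaults emulate the study conditions of the cold-tolerance
#' experiments: per-stage mortality curves back-solved from published
#' lethality estimates for larvae reared in 'Hayward' kiwifruit (so the
#' generating `alpha`/`beta` reproduce those LT_50 and LT_99.9968
#' values), a cultivar susceptibility shift on the link scale for
#' 'Zesy002', egg loads per fruit matching the printed infestation means
#' (90 eggs, and 105 for the large-scale design) with standard
#' deviations back-solved from their 95% CIs at n = 30, survival-to-pupa
#' rates implied by control-box yields (about 0.70 in 'Hayward', 0.27 in
#' 'Zesy002'), and 51 pupae per fruit in the large-scale controls.
#' Between-box overdispersion (`rho` about 0.05) and a replicate
#' standard deviation of 0.2 on the link scale are synthetic choices
#' large enough that dispersion diagnostics can detect non-binomial
#' variance.
#'
#' @param ... Named overrides of any default element.
#' @return A list of class `tm_params`.
#' @export
default_params <- function(...) {
  stages <- c("egg", "L1", "L2", "L3")
  lt50 <- c(egg = 3.85, L1 = 2.29, L2 = 3.33, L3 = 4.05)
  lt_p9 <- c(egg = 16.32, L1 = 9.97, L2 = 13.81, L3 = 17.31)
  q9 <- stats::qlogis(probit9)
  beta <- q9 / (lt_p9 - lt50)
  alpha <- -beta * lt50
  p <- list(
    link = "logit",
    stages = stages,
    alpha = alpha,
    beta = beta,
    cultivar_shift = 0.5,          # Zesy002 more susceptible, link scale
    disp_intercept = stats::setNames(rep(stats::qlogis(0.05), 4), stages),
    disp_slope = 0,
    sigma_u = 0.2,
    eggs_per_fruit = list(y2018 = c(mean = 90, sd = 21.7),
                          y2019 = c(mean = 90, sd = 21.7),
                          large = c(mean = 105, sd = 8.3)),
    survival_to_pupa = c(Hayward = 0.70, Zesy002 = 0.27),
    large_pupae_per_fruit = c(mean = 51, sd = 5.4),
    large_survival = c(d8 = 0.02, d10 = 0.0045, d18 = 0),
    dissect_l3_per_fruit = c(mean = 78, sd = 4.8))
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  class(p) <- "tm_params"
  p
}

#' True lethal time implied by generator parameters
#'
#' @param params A [default_params()] list.
#' @param stage Life stage.
#' @param p Mortality level.
#' @param cultivar `"Hayward"` (baseline) or `"Zesy002"` (shifted).
#' @return Days.
#' @export
lt_true <- function(params, stage, p = probit9, cultivar = "Hayward") {
  a <- params$alpha[stage] + if (cultivar == "Zesy002") params$cultivar_shift else 0
  unname((link_transform(p, params$link) - a) / params$beta[stage])
}

#' Generate a box-level cold-tolerance bioassay dataset
#'
#' Simulates the box-level records of a cold-tolerance experiment with
#' known ground truth. The 2018-style design crosses 4 life stages, 2
#' cultivars, durations 0/5/6/7/8/10 days, 4 replicates, 3 boxes per
#' cell and 5 fruit per box; the 2019-style design tests third instars
#' only at durations 0/8/10/11/13/14/16/18 days with 5 boxes of 10
#' fruit (810 fruit infested per replicate including 10 set aside for
#' dissection). Egg loads per fruit are rounded-normal draws truncated
#' at 1; the insects that would pupate untreated are binomial thins of
#' the egg load; treated-box survivors are beta-binomial draws with
#' mortality from the link model plus Gaussian replicate intercepts.
#' The `treated_estimate` column is computed from the simulated control
#' boxes exactly as the analysis pipeline would; the per-box treatable
#' truth is bookkept in the `truth` attribute.
#'
#' @param design `"y2018"`, `"y2019"`, or `"custom"` (supply
#'   `durations`, `stages`, `cultivars`, `n_rep`, `boxes`, `fruit_per_box`).
#' @param params A [default_params()] list.
#' @param seed Integer seed; the dataset is a pure function of
#'   (design, params, seed).
#' @param durations,stages,cultivars,n_rep,boxes,fruit_per_box Custom
#'   design knobs (ignored unless `design = "custom"`).
#'
#' @return A data frame of box-level records (`year`, `cultivar`,
#'   `life_stage`, `replicate`, `duration_days`, `unit_id`,
#'   `pupae_count`, `treated_estimate`) with attributes `params` (echo)
#'   and `truth` (per-box `n_treatable` and true mortality).
#' @export
gen_cold_tolerance <- function(design = c("y2018", "y2019", "custom"),
                               params = default_params(), seed = 1,
                               durations = NULL, stages = NULL,
                               cultivars = c("Hayward", "Zesy002"),
                               n_rep = 4, boxes = 3, fruit_per_box = 5) {
  design <- match.arg(design)
  if (design == "y2018") {
    durations <- c(0, 5, 6, 7, 8, 10); stages <- params$stages
    boxes <- 3; fruit_per_box <- 5; year <- "2018"; egg_key <- "y2018"
  } else if (design == "y2019") {
    durations <- c(0, 8, 10, 11, 13, 14, 16, 18); stages <- "L3"
    boxes <- 5; fruit_per_box <- 10; year <- "2019"; egg_key <- "y2019"
  } else {
    if (is.null(durations) || is.null(stages)) {
      stop("custom design requires `durations` and `stages`", call. = FALSE)
    }
    year <- "custom"; egg_key <- "y2018"
  }
  eggs <- params$eggs_per_fruit[[egg_key]]
  with_seed(seed, {
    u_rep <- stats::setNames(stats::rnorm(n_rep, 0, params$sigma_u), seq_len(n_rep))
    grid <- expand.grid(cultivar = cultivars, life_stage = stages,
                        replicate = seq_len(n_rep), duration_days = durations,
                        box = seq_len(boxes), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    n <- nrow(grid)
    egg_load <- vapply(seq_len(n), function(i) {
      sum(pmax(round(stats::rnorm(fruit_per_box, eggs["mean"], eggs["sd"])), 1))
    }, numeric(1))
    surv <- params$survival_to_pupa[grid$cultivar]
    n_treatable <- stats::rbinom(n, egg_load, surv)
    n_treatable <- pmax(n_treatable, 1)
    shift <- ifelse(grid$cultivar == "Zesy002", params$cultivar_shift, 0)
    eta <- params$alpha[grid$life_stage] + shift +
      u_rep[as.character(grid$replicate)] +
      params$beta[grid$life_stage] * grid$duration_days
    p_die <- pmin(pmax(link_inverse(eta, params$link), 1e-12), 1 - 1e-12)
    rho <- pmin(stats::plogis(params$disp_intercept[grid$life_stage] +
                                params$disp_slope * grid$duration_days), 1 - 1e-10)
    pupae <- integer(n)
    ctrl <- grid$duration_days == 0
    pupae[ctrl] <- n_treatable[ctrl]
    if (any(!ctrl)) {
      i <- which(!ctrl)
      pupae[i] <- rbetabinom(length(i), n_treatable[i], 1 - p_die[i], rho[i])
    }
    out <- data.frame(year = year, cultivar = grid$cultivar,
                      life_stage = grid$life_stage,
                      replicate = grid$replicate,
                      duration_days = grid$duration_days,
                      unit_id = sprintf("%s_%s_%s_r%d_d%g_b%d", year,
                                        substr(grid$cultivar, 1, 3),
                                        grid$life_stage, grid$replicate,
                                        grid$duration_days, grid$box),
                      pupae_count = pupae, stringsAsFactors = FALSE)
    if (any(ctrl)) {
      out <- estimate_treated(out)
    } else {
      # designs without control boxes fall back to the bookkept truth
      out$treated_estimate <- n_treatable
    }
    attr(out, "params") <- params
    attr(out, "truth") <- data.frame(unit_id = out$unit_id,
                                     n_treatable = n_treatable,
                                     p_die = ifelse(ctrl, 0, p_die),
                                     stringsAsFactors = FALSE)
    out
  })
}

#' Generate large-scale-trial count sets
#'
#' Three replicates with the large-scale design's fruit numbers: 200
#' control fruit, 180 fruit at each of the 8- and 10-day durations,
#' 3,400 fruit at 18 days, and 10 dissection fruit (3,770 infested per
#' replicate). Control pupae are rounded-normal per-fruit yields;
#' treated-lot survivors are binomial draws at the configured survival
#' probabilities (zero at 18 days under a treatment exceeding the
#' probit-9 level).
#'
#' @param params A [default_params()] list.
#' @param seed Integer seed.
#' @return A list with `controls` (3 totals), `dissections` (per-fruit
#'   L3 counts by replicate), `treated` (days x replicate survivor and
#'   true-treated counts), `n_fruit` bookkeeping, and a `params` echo.
#' @export
gen_large_scale <- function(params = default_params(), seed = 1) {
  ppf <- params$large_pupae_per_fruit
  with_seed(seed, {
    controls <- vapply(1:3, function(r) {
      sum(pmax(round(stats::rnorm(200, ppf["mean"], ppf["sd"])), 0))
    }, numeric(1))
    dissections <- do.call(rbind, lapply(1:3, function(r) {
      data.frame(replicate = r, fruit = 1:10,
                 l3 = pmax(round(stats::rnorm(10, params$dissect_l3_per_fruit["mean"],
                                              params$dissect_l3_per_fruit["sd"])), 0))
    }))
    days <- c(8, 10, 18)
    nf <- c(180, 180, 3400)
    sv <- unname(params$large_survival[c("d8", "d10", "d18")])
    treated <- do.call(rbind, lapply(1:3, function(r) {
      n_true <- vapply(nf, function(k) {
        sum(pmax(round(stats::rnorm(k, ppf["mean"], ppf["sd"])), 0))
      }, numeric(1))
      data.frame(replicate = r, days_treated = days, n_fruit = nf,
                 n_true = n_true,
                 survivors = stats::rbinom(3, n_true, sv))
    }))
    list(controls = controls, dissections = dissections, treated = treated,
         n_fruit = list(control = 200, d8 = 180, d10 = 180, d18 = 3400,
                        dissect = 10, per_replicate = 3770),
         params = params)
  })
}

#' Generate a multi-probe cold-store temperature log
#'
#' Fruit-core probes follow exponential-decay cooling toward the plateau
#' temperature with Gaussian reading noise; air probes cool with a much
#' shorter time constant. The analytic 3.5 degC crossing time of the
#' noise-free fruit curve, `tau * log((start - plateau)/(3.5 - plateau))`,
#' is recorded as ground truth.
#'
#' @param start_c Initial fruit-core temperature (degC).
#' @param plateau_c Plateau temperature (degC); must be below 3.5 for
#'   the crossing to exist.
#' @param time_constant_h Exponential time constant (hours).
#' @param noise_sd Reading noise standard deviation (degC).
#' @param n_probes Number of fruit-core probes.
#' @param n_air Number of air probes.
#' @param interval_min Sampling interval (minutes; default 30).
#' @param duration_h Log length (hours).
#' @param seed Integer seed.
#' @param origin Timestamp of loading (POSIXct or ISO string).
#'
#' @return A long data frame (`probe_id`, `probe_kind`, `timestamp`,
#'   `reading_c`) with attribute `truth` holding the analytic crossing
#'   time in hours (0 when the start is already below 3.5).
#' @export
gen_temperature_log <- function(start_c = 25, plateau_c = 3.0,
                                time_constant_h = 14, noise_sd = 0.1,
                                n_probes = 10, n_air = 6, interval_min = 30,
                                duration_h = 432, seed = 1,
                                origin = "2022-01-11T00:00:00") {
  stopifnot(duration_h > 0, interval_min > 0)
  t0 <- as.POSIXct(origin, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  hrs <- seq(0, duration_h, by = interval_min / 60)
  crossing <- if (start_c < 3.5) 0 else if (plateau_c >= 3.5) NA_real_ else
    time_constant_h * log((start_c - plateau_c) / (3.5 - plateau_c))
  curve <- function(tau) plateau_c + (start_c - plateau_c) * exp(-hrs / tau)
  with_seed(seed, {
    mk <- function(id, kind, tau) {
      data.frame(probe_id = id, probe_kind = kind,
                 timestamp = t0 + hrs * 3600,
                 reading_c = curve(tau) + stats::rnorm(length(hrs), 0, noise_sd),
                 stringsAsFactors = FALSE)
    }
    logs <- rbind(
      do.call(rbind, lapply(seq_len(n_probes), function(i) {
        mk(sprintf("fruit%02d", i), "fruit", time_constant_h)
      })),
      if (n_air > 0) do.call(rbind, lapply(seq_len(n_air), function(i) {
        mk(sprintf("air%02d", i), "air", 1)
      })))
    attr(logs, "truth") <- list(crossing_h = crossing, start_c = start_c,
                                plateau_c = plateau_c,
                                time_constant_h = time_constant_h)
    logs
  })
}
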