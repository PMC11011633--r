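#' Published duration-level bioassay totals
#'
#' Duration-level totals from the 2018 and 2019 cold-tolerance
#' experiments on immature Mediterranean fruit fly (*Ceratitis
#' capitata*) in 'Hayward' and 'Zesy002' kiwifruit treated at 3 degC:
#' for each cultivar, life stage (egg, L1, L2, L3) and treatment
#' duration, the number of boxes treated (`n_units`), the total pupae
#' retrieved (`pupae_count`, the survivors), and the estimated number
#' treated (`treated_estimate`, derived from control-box yields). Third
#' instars were also tested at the longer 2019 durations (11-18 days).
#' These totals support the scaled-down duration-level refits shipped
#' with the package; the original box-level records are not public.
#'
#' @param cultivar `"both"`, `"Hayward"`, or `"Zesy002"`.
#' @param stage `"all"` or a subset of `c("egg", "L1", "L2", "L3")`.
#' @return Data frame with columns `cultivar`, `life_stage`,
#'   `duration_days`, `n_units`, `pupae_count`, `treated_estimate`.
#'
#' @examples
#' head(cold_tolerance_totals("Hayward", "L3"))
#' @export
cold_tolerance_totals <- function(cultivar = c("both", "Hayward", "Zesy002"),
                                  stage = "all") {
  cultivar <- match.arg(cultivar)
  d6 <- c(0, 5, 6, 7, 8, 10)
  d11 <- c(d6, 11, 13, 14, 16, 18)
  row <- function(cv, st, d, n, p, e) {
    data.frame(cultivar = cv, life_stage = st, duration_days = d,
               n_units = n, pupae_count = p, treated_estimate = e,
               stringsAsFactors = FALSE)
  }
  hay <- rbind(
    row("Hayward", "egg", d6, c(12, 12, 12, 12, 12, 12),
        c(2892, 973, 575, 232, 121, 2),
        c(3082, 2898, 2898, 2898, 2898, 2898)),
    row("Hayward", "L1", d6, c(12, 12, 12, 12, 12, 12),
        c(2420, 81, 16, 3, 1, 0),
        c(2560, 2427, 2427, 2427, 2427, 2427)),
    row("Hayward", "L2", d6, c(12, 12, 12, 12, 12, 12),
        c(2371, 399, 292, 78, 12, 2),
        c(2473, 2376, 2376, 2360, 2376, 2376)),
    row("Hayward", "L3", d11, c(32, 12, 12, 12, 32, 31, 20, 19, 20, 20, 20),
        c(10039, 1176, 483, 242, 382, 55, 16, 1, 3, 0, 0),
        c(10964, 2469, 2469, 2404, 10044, 9491, 7575, 7244, 7575, 7575, 7575)))
  zes <- rbind(
    row("Zesy002", "egg", d6, c(12, 12, 12, 12, 12, 12),
        c(1597, 466, 335, 142, 41, 0),
        c(1766, 1602, 1602, 1602, 1602, 1602)),
    row("Zesy002", "L1", d6, c(12, 12, 12, 12, 12, 12),
        c(1220, 161, 61, 38, 17, 0),
        c(1294, 1224, 1224, 1224, 1224, 1224)),
    row("Zesy002", "L2", d6, c(12, 12, 12, 12, 12, 12),
        c(1402, 255, 108, 65, 14, 0),
        c(1593, 1407, 1407, 1407, 1407, 1407)),
    row("Zesy002", "L3", d11, c(32, 12, 12, 12, 31, 32, 20, 20, 20, 20, 20),
        c(3875, 467, 310, 177, 97, 16, 0, 0, 1, 0, 0),
        c(4404, 1710, 1710, 1710, 3817, 3875, 2165, 2165, 2165, 2165, 2165)))
  out <- rbind(hay, zes)
  if (cultivar != "both") out <- out[out$cultivar == cultivar, , drop = FALSE]
  if (!identical(stage, "all")) out <- out[out$life_stage %in% stage, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Published large-scale-trial pupal counts
#'
#' Pupae recovered in the 2022 large-scale trial: per-replicate totals
#' from the 200 control fruit and from the fruit treated for 8, 10, and
#' 18 days (3 replicates; 180, 180, and 3,400 treated fruit per
#' replicate respectively).
#'
#' @return Data frame with columns `days_treated`, `n_fruit`,
#'   `rep1`, `rep2`, `rep3`.
#' @export
large_scale_counts <- function() {
  data.frame(days_treated = c(0, 8, 10, 18),
             n_fruit = c(200, 180, 180, 3400),
             rep1 = c(10226, 187, 41, 0),
             rep2 = c(10598, 188, 37, 0),
             rep3 = c(10625, 188, 40, 0))
}
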