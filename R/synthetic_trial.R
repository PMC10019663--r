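#' Simulate an episode-level trial table
#'
#' Generates a synthetic dataset with the statistical structure of the HS2
#' trial's episode table, so that every estimator feeding the economic model
#' (per-arm repeat rates, time-of-day split, conveyance proportion, added
#' at-scene time) can be exercised without external data. Each row is one
#' see-treat-and-refer episode with: arm, a Bernoulli repeat-within-14-days
#' flag, a Bernoulli day/night stratum, a Bernoulli conveyed-to-ED flag and
#' an at-scene duration in minutes.
#'
#' Durations are drawn from a log-normal base common to both arms with a
#' deterministic additive shift in the intervention arm (6.6 minutes for
#' in-hours episodes, 2 minutes overnight by default), so the arm difference
#' in median duration per stratum equals the shift in expectation. Only
#' these aggregates are emulated; no patient-identifiable or calendar
#' structure is generated.
#'
#' @param n_hs2,n_sc Episodes per arm (defaults 707 and 1674).
#' @param p_hs2,p_sc Per-arm repeat probabilities (defaults 4.5% and 5.5%).
#' @param day_share Proportion of episodes occurring 8am-8pm (default 0.28).
#' @param convey_p Conveyance-to-ED probability (default 0.6).
#' @param duration List with `meanlog`, `sdlog` of the base at-scene
#'   duration and `added` (named vector `day`, `night`) of intervention-arm
#'   shifts in minutes.
#' @param seed Optional integer seed.
#' @return A tibble with columns `arm` (`"hs2"`/`"sc"`), `repeat14`,
#'   `stratum` (`"day"`/`"night"`), `conveyed`, `duration_mins`.
#' @export
#' @examples
#' tab <- simulate_trial(seed = 1)
#' table(tab$arm)
simulate_trial <- function(n_hs2 = 707, p_hs2 = 0.045,
                           n_sc = 1674, p_sc = 0.055,
                           day_share = 0.28, convey_p = 0.6,
                           duration = list(meanlog = log(30), sdlog = 0.45,
                                           added = c(day = 6.6, night = 2)),
                           seed = NULL) {
  check_prob(c(p_hs2, p_sc), "repeat probabilities")
  check_prob(day_share, "day_share")
  check_prob(convey_p, "convey_p")
  if (n_hs2 < 1 || n_sc < 1) stop("arm sizes must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- n_hs2 + n_sc
  arm <- rep(c("hs2", "sc"), c(n_hs2, n_sc))
  stratum <- ifelse(stats::runif(n) < day_share, "day", "night")
  base <- stats::rlnorm(n, duration$meanlog, duration$sdlog)
  shift <- ifelse(arm == "hs2", duration$added[stratum], 0)
  tibble::tibble(
    arm = arm,
    repeat14 = stats::runif(n) < ifelse(arm == "hs2", p_hs2, p_sc),
    stratum = stratum,
    conveyed = stats::runif(n) < convey_p,
    duration_mins = base + shift
  )
}

#' Estimate model inputs from an episode table
#'
#' The bridge from raw episode data to the model's transition parameters and
#' intervention cost: per-arm repeat-attendance proportions (the calibration
#' targets for the severity probabilities), the conveyance proportion, the
#' day-time share, the arm difference in median at-scene duration per
#' stratum and the day-share-weighted added administration time (via
#' [weighted_admin_time()]).
#'
#' @param table An episode tibble as produced by [simulate_trial()].
#' @return A list with `repeat_rate` (named `hs2`, `sc`), `n` (arm sizes),
#'   `convey_p`, `day_share`, `median_added` (named `day`, `night`) and
#'   `admin_minutes`.
#' @export
estimate_model_inputs <- function(table) {
  stopifnot(all(c("arm", "repeat14", "stratum", "conveyed",
                  "duration_mins") %in% names(table)))
  for (a in c("hs2", "sc")) {
    if (!any(table$arm == a)) {
      stop("episode table has no rows for arm ", a, call. = FALSE)
    }
  }
  split_arm <- split(table, table$arm)
  repeat_rate <- vapply(split_arm, function(d) mean(d$repeat14), numeric(1))
  n <- vapply(split_arm, nrow, integer(1))
  day_share <- mean(table$stratum[table$arm == "hs2"] == "day")
  med_diff <- vapply(c(day = "day", night = "night"), function(s) {
    h <- table$duration_mins[table$arm == "hs2" & table$stratum == s]
    c <- table$duration_mins[table$arm == "sc" & table$stratum == s]
    if (!length(h) || !length(c)) return(NA_real_)
    stats::median(h) - stats::median(c)
  }, numeric(1))
  present <- !is.na(med_diff)
  admin <- if (all(present)) {
    weighted_admin_time(day_share, med_diff[["day"]], med_diff[["night"]])
  } else {
    # single-stratum table: the weighted time is that stratum's difference
    med_diff[present][[1]]
  }
  list(
    repeat_rate = c(hs2 = unname(repeat_rate["hs2"]),
                    sc = unname(repeat_rate["sc"])),
    n = c(hs2 = unname(n["hs2"]), sc = unname(n["sc"])),
    convey_p = mean(table$conveyed),
    day_share = day_share,
    median_added = med_diff,
    admin_minutes = unname(admin)
  )
}

#' Build a configuration from estimated trial inputs
#'
#' Replaces the observed repeat-attendance rates, trial arm sizes, day share
#' and added administration minutes of a base configuration with estimates
#' from an episode table, and recomputes the intervention state cost from the
#' estimated administration time. The result feeds the full analysis
#' pipeline, closing the loop from raw data to model outputs.
#'
#' @param inputs An [estimate_model_inputs()] result.
#' @param config Base configuration to modify.
#' @return A validated `hs2_config`.
#' @export
config_from_trial <- function(inputs, config = default_config()) {
  config$transitions$hs2$observed_repeat_rate <- inputs$repeat_rate[["hs2"]]
  config$transitions$sc$observed_repeat_rate <- inputs$repeat_rate[["sc"]]
  config$trial$hs2[["n"]] <- inputs$n[["hs2"]]
  config$trial$sc[["n"]] <- inputs$n[["sc"]]
  config$trial$day_share <- inputs$day_share
  config$trial$convey_p <- inputs$convey_p
  if (all(!is.na(inputs$median_added))) {
    config$trial$added_minutes <- c(day = inputs$median_added[["day"]],
                                    night = inputs$median_added[["night"]])
  }
  config$state_costs$intervention$cost <- intervention_cost(
    inputs$admin_minutes,
    unit_cost(config, "HS2_admin"),
    unit_cost(config, "HS2_booklet")
  )
  validate_config(config)
  config
}
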