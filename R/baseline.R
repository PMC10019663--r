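#' Incremental cost-effectiveness ratio with dominance flags
#'
#' Ratio of the incremental cost to the incremental effect of the
#' intervention over its comparator. Sign conventions: positive incremental
#' cost means the intervention is costlier, positive incremental effect means
#' it is more effective. When the signs differ the ratio is not informative
#' on its own and a dominance flag is set instead: `"dominant"` (cheaper and
#' more effective) or `"dominated"` (costlier and less effective). A zero
#' effect difference yields an undefined ICER, signalled rather than
#' returned as a number.
#'
#' @param delta_cost Incremental cost (GBP per patient).
#' @param delta_effect Incremental effect (probability of the outcome
#'   avoided; an ICER per whole case uses the same ratio).
#' @return A list with `value` (NA when undefined), `defined`, and
#'   `dominance` (`"dominant"`, `"dominated"` or `NA`).
#' @export
#' @examples
#' icer(9.29, 0.030)$value # 309.67
icer <- function(delta_cost, delta_effect) {
  stopifnot(length(delta_cost) == 1L, length(delta_effect) == 1L)
  dominance <- if (delta_cost < 0 && delta_effect > 0) {
    "dominant"
  } else if (delta_cost > 0 && delta_effect < 0) {
    "dominated"
  } else {
    NA_character_
  }
  if (delta_effect == 0) {
    return(list(value = NA_real_, defined = FALSE, dominance = dominance))
  }
  list(value = delta_cost / delta_effect, defined = TRUE,
       dominance = dominance)
}

#' Relative change in the risk of recurrence
#'
#' Relative difference of the two arms' no-recurrence probabilities,
#' `(p0_int - p0_comp) / p0_comp`, expressed as a percentage. A positive
#' value is the relative-risk reduction of recurrent hypoglycaemia achieved
#' by the intervention.
#'
#' @param p0_int,p0_comp No-recurrence probabilities under the intervention
#'   and the comparator.
#' @return Percentage (full precision; report to 1 dp).
#' @export
#' @examples
#' relative_risk_reduction(0.42404, 0.39400) # 7.6 to 1 dp
relative_risk_reduction <- function(p0_int, p0_comp) {
  check_prob(p0_int, "p0_int")
  check_prob(p0_comp, "p0_comp")
  if (p0_comp == 0) stop("comparator probability must be > 0", call. = FALSE)
  100 * (p0_int - p0_comp) / p0_comp
}

#' Two-proportion z-test of equal event rates
#'
#' Pooled-variance two-proportion z statistic with a two-sided normal
#' p-value and no continuity correction; the test applied to the trial's
#' primary outcome (repeat EMS attendance within a fortnight by arm). All
#' arguments are vectorised.
#'
#' @param events1,n1 Events and trials in the first group.
#' @param events2,n2 Events and trials in the second group.
#' @return A list of vectors: `p1`, `p2`, `z`, `p_value`.
#' @export
#' @examples
#' efficacy_test(32, 707, 92, 1674)$p_value # 0.33 to 2 dp
efficacy_test <- function(events1, n1, events2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) {
    stop("group sizes must be positive", call. = FALSE)
  }
  if (any(events1 < 0) || any(events1 > n1) ||
      any(events2 < 0) || any(events2 > n2)) {
    stop("event counts must lie in [0, n]", call. = FALSE)
  }
  p1 <- events1 / n1
  p2 <- events2 / n2
  pooled <- (events1 + events2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- ifelse(se == 0, 0, (p1 - p2) / se)
  list(p1 = p1, p2 = p2, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Baseline cost-effectiveness analysis
#'
#' Evaluates both calibrated arms and assembles the baseline
#' cost-effectiveness result: average per-patient cost by service provider
#' and in total for each arm, the cost difference, the no-recurrence
#' probabilities and their difference, the relative-risk reduction and the
#' ICER in GBP per episode of recurrent hypoglycaemia avoided.
#'
#' @param config Model configuration.
#' @return A list of class `hs2_cea` with elements `costs` (tibble by
#'   provider and arm), `p0_hs2`, `p0_sc`, `delta_cost`, `delta_effect`,
#'   `rrr_percent` and `icer` (the [icer()] list).
#' @export
#' @examples
#' res <- run_baseline()
#' res$p0_hs2 # 0.424
run_baseline <- function(config = default_config()) {
  validate_config(config)
  ev_h <- arm_evaluate("hs2", config)
  ev_s <- arm_evaluate("sc", config)
  costs <- tibble::tibble(
    provider = c(PROVIDERS, "total"),
    hs2 = unname(c(ev_h$cost[1, ], ev_h$total)),
    sc = unname(c(ev_s$cost[1, ], ev_s$total))
  )
  costs$difference <- costs$hs2 - costs$sc
  delta_cost <- ev_h$total - ev_s$total
  delta_effect <- ev_h$p0 - ev_s$p0
  structure(list(
    costs = costs,
    p0_hs2 = ev_h$p0, p0_sc = ev_s$p0,
    p4 = ev_h$p4, q4 = ev_s$p4,
    outcome_hs2 = outcome_dist(ev_h$p0, ev_h$p_ns, ev_h$p_s),
    outcome_sc = outcome_dist(ev_s$p0, ev_s$p_ns, ev_s$p_s),
    delta_cost = delta_cost,
    delta_effect = delta_effect,
    rrr_percent = relative_risk_reduction(ev_h$p0, ev_s$p0),
    icer = icer(delta_cost, delta_effect)
  ), class = "hs2_cea")
}

#' @export
print.hs2_cea <- function(x, ...) {
  cat("Baseline cost-effectiveness analysis\n")
  cat(sprintf("  cost/patient: HS2 £%.2f vs SC £%.2f (difference £%.2f)\n",
              x$costs$hs2[5], x$costs$sc[5], x$delta_cost))
  cat(sprintf("  P(no recurrence): %.1f%% vs %.1f%% (RRR %.1f%%)\n",
              100 * x$p0_hs2, 100 * x$p0_sc, x$rrr_percent))
  if (x$icer$defined) {
    cat(sprintf("  ICER: £%.2f per recurrence avoided\n", x$icer$value))
  } else {
    cat("  ICER: undefined (zero effect difference)\n")
  }
  invisible(x)
}

# Apply a one-way perturbation to a configuration. Severe-rate scenarios
# change the observed rate only; calibration is re-run when the arm is
# rebuilt.
apply_scenario <- function(config, parameter, value) {
  switch(parameter,
    intervention_cost = {
      if (value < 0) stop("intervention cost must be >= 0", call. = FALSE)
      config$state_costs$intervention$cost <- value
    },
    r_hs2 = {
      if (value <= 0 || value >= config$transitions$r_max) {
        stop("r_hs2 must lie in (0, r_max)", call. = FALSE)
      }
      config$transitions$hs2$rates["read_action"] <- value
      config$transitions$sc$rates["action"] <- value
    },
    hs2_severe_rate = {
      check_prob(value, "hs2_severe_rate")
      config$transitions$hs2$observed_repeat_rate <- value
    },
    stop("unknown scenario parameter: ", parameter, call. = FALSE)
  )
  config
}

#' Default one-way sensitivity scenarios
#'
#' The three shipped scenarios: (i) intervention cost confined to
#' out-of-hours (2 added minutes, cost 6.70) versus in-hours administration
#' (6.6 minutes, 18.43); (ii) the full-success incident rate halved to 0.375
#' versus raised to 0.9; (iii) the HS2 severe-recurrence rate lowered to
#' 3.5% versus raised to the standard-care 5.5%.
#'
#' @param config Model configuration (supplies cost components).
#' @return A list of scenario definitions.
#' @export
default_scenarios <- function(config = default_config()) {
  admin <- unit_cost(config, "HS2_admin")
  booklet <- unit_cost(config, "HS2_booklet")
  mins <- config$trial$added_minutes
  list(
    list(name = "intervention cost", parameter = "intervention_cost",
         low = intervention_cost(mins[["night"]], admin, booklet),
         high = intervention_cost(mins[["day"]], admin, booklet),
         baseline = config$state_costs$intervention$cost),
    list(name = "recurrence rate r_hs2", parameter = "r_hs2",
         low = 0.375, high = 0.9,
         baseline = unname(config$transitions$hs2$rates[["read_action"]])),
    list(name = "HS2 severe recurrence rate", parameter = "hs2_severe_rate",
         low = 0.035, high = 0.055,
         baseline = config$transitions$hs2$observed_repeat_rate)
  )
}

#' One-way sensitivity analysis with tornado ordering
#'
#' Re-runs the baseline analysis with each scenario parameter set to its low
#' and high value, all other parameters held at baseline. Severe-rate
#' scenarios re-run the calibration of the severity probability. Scenarios
#' whose perturbed value is infeasible are reported with an `error` message
#' and do not stop the run. The result is ordered for a tornado diagram
#' (widest ICER range first).
#'
#' @param config Model configuration.
#' @param scenarios A list of scenarios as produced by [default_scenarios()].
#' @return A tibble of class `hs2_sensitivity` with columns `name`,
#'   `parameter`, `low`, `high`, `baseline`, `icer_low`, `icer_high`,
#'   `icer_baseline`, `range` and `error`.
#' @export
one_way_sensitivity <- function(config = default_config(),
                                scenarios = default_scenarios(config)) {
  base_icer <- run_baseline(config)$icer$value
  rows <- lapply(scenarios, function(sc) {
    stopifnot(sc$baseline >= min(sc$low, sc$high),
              sc$baseline <= max(sc$low, sc$high))
    run_one <- function(value) {
      run_baseline(apply_scenario(config, sc$parameter, value))$icer$value
    }
    res <- tryCatch(
      list(low = run_one(sc$low), high = run_one(sc$high), error = NA_character_),
      error = function(e) list(low = NA_real_, high = NA_real_,
                               error = conditionMessage(e))
    )
    tibble::tibble(
      name = sc$name, parameter = sc$parameter,
      low = sc$low, high = sc$high, baseline = sc$baseline,
      icer_low = res$low, icer_high = res$high,
      icer_baseline = base_icer,
      range = abs(res$high - res$low),
      error = res$error
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), ]
  structure(out, class = c("hs2_sensitivity", class(out)))
}
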