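#' Convert a per-fortnight incident rate to a recurrence probability
#'
#' Under an exponentially distributed time to incident with rate `r` per
#' fortnight, the probability of at least one recurrence within the fortnight
#' is `1 - exp(-r)`. The map is strictly increasing with range \[0, 1).
#'
#' @param r Non-negative per-fortnight incident rate (vectorised).
#' @return Probability of recurrence within the fortnight.
#' @seealso [probability_to_rate()] for the inverse.
#' @export
#' @examples
#' rate_to_probability(0.75) # 0.53 to 2 dp
rate_to_probability <- function(r) {
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("incident rate must be finite and >= 0", call. = FALSE)
  }
  1 - exp(-r)
}

#' @rdname rate_to_probability
#' @param p Probability in \[0, 1).
#' @export
probability_to_rate <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("probability must lie in [0, 1)", call. = FALSE)
  }
  -log(1 - p)
}

#' Scale an annual incidence per 1,000 person-years to a per-fortnight rate
#'
#' Divides by 1,000 persons and by the 26 fortnights of a year. The published
#' incidence range of 0.072 to 42,890 episodes per 1,000 person-years scales
#' to 2.8e-6 to 1.65 episodes per person per fortnight, the latter being the
#' upper rate bound used throughout the model.
#'
#' @param annual_rate_per_1000 Episodes per 1,000 person-years (vectorised).
#' @return Episodes per person per fortnight.
#' @export
#' @examples
#' annual_rate_to_fortnight(42890) # 1.65
annual_rate_to_fortnight <- function(annual_rate_per_1000) {
  if (any(!is.finite(annual_rate_per_1000)) || any(annual_rate_per_1000 < 0)) {
    stop("annual rate must be finite and >= 0", call. = FALSE)
  }
  annual_rate_per_1000 * 1e-3 / 26
}

#' Intervention cost from its components
#'
#' The HS2 intervention cost is the booklet production cost plus the
#' ambulance-crew time cost of administering it: issuing and filling in the
#' booklet and, during business hours, organising a next-day GP appointment.
#'
#' @param admin_minutes Administration time in minutes.
#' @param per_minute_cost Dual-crewed ambulance cost per minute (GBP);
#'   default 2.55.
#' @param booklet_cost Production cost of the booklet (GBP); default 1.60.
#' @return Cost in GBP.
#' @export
#' @examples
#' intervention_cost(2)    # out-of-hours administration: 6.70
#' intervention_cost(6.6)  # in-hours administration: 18.43
intervention_cost <- function(admin_minutes, per_minute_cost = 2.55,
                              booklet_cost = 1.60) {
  if (any(admin_minutes < 0) || any(per_minute_cost < 0) ||
      any(booklet_cost < 0)) {
    stop("intervention cost components must be >= 0", call. = FALSE)
  }
  booklet_cost + per_minute_cost * admin_minutes
}

#' Day-share-weighted administration time
#'
#' Weighted average of the in-hours and overnight added at-scene durations by
#' the proportion of episodes occurring in the 8am-8pm period.
#'
#' @param day_share Proportion of episodes in hours, in \[0, 1\].
#' @param day_minutes,night_minutes Added minutes in each stratum.
#' @return Weighted minutes (full precision; round to 1 dp for reporting).
#' @export
#' @examples
#' weighted_admin_time(0.28, 6.6, 2) # 3.3 to 1 dp
weighted_admin_time <- function(day_share, day_minutes, night_minutes) {
  if (any(day_share < 0) || any(day_share > 1)) {
    stop("day_share must lie in [0, 1]", call. = FALSE)
  }
  if (any(day_minutes < 0) || any(night_minutes < 0)) {
    stop("minutes must be >= 0", call. = FALSE)
  }
  day_share * day_minutes + (1 - day_share) * night_minutes
}

#' Expected cost of self-managed non-severe recurrence
#'
#' Self-management of a non-severe recurrence is predominantly self-care at
#' no NHS cost but may involve self-transport to an emergency department.
#' The expected cost is the dot product of a 5-way outcome mix (ED types 1-4
#' not admitted, then zero-cost self-care) with the corresponding unit costs.
#'
#' @param mix Numeric vector of 5 proportions summing to 1 (see
#'   `default_config()$self_manage`).
#' @param schedule Cost schedule (or whole config).
#' @return Expected cost in GBP.
#' @export
#' @examples
#' cfg <- default_config()
#' self_manage_cost(cfg$self_manage$read_action, cfg) # 25.03
#' self_manage_cost(cfg$self_manage$other, cfg)       # 33.54
self_manage_cost <- function(mix, schedule) {
  if (length(mix) != 5L) {
    stop("self-manage mix must have 5 proportions", call. = FALSE)
  }
  check_prob(mix, "self-manage mix")
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("self-manage mix must sum to 1", call. = FALSE)
  }
  costs <- c(unit_cost(schedule, "ED1NA"), unit_cost(schedule, "ED2NA"),
             unit_cost(schedule, "ED3NA"), unit_cost(schedule, "ED4NA"), 0)
  sum(mix * costs)
}

#' Annual population eligible for the intervention
#'
#' Number of patients per year eligible to receive the at-scene referral:
#' total emergency attendances, scaled by the proportion that are for severe
#' hypoglycaemia, excluding repeat attendances within two weeks and cases
#' conveyed to an emergency department (only at-scene resolutions are
#' eligible).
#'
#' @param attendances Annual ambulance attendances.
#' @param hypo_rate Proportion of attendances for severe hypoglycaemia.
#' @param repeat_frac Proportion that are repeats within two weeks.
#' @param convey_frac Proportion conveyed to ED.
#' @return List with `exact` count and `rounded` (nearest thousand).
#' @export
#' @examples
#' eligible_population(7.9e6, 0.006, 0.05, 0.6) # about 18,000 per year
eligible_population <- function(attendances, hypo_rate, repeat_frac,
                                convey_frac) {
  if (attendances < 0) stop("attendances must be >= 0", call. = FALSE)
  check_prob(hypo_rate, "hypo_rate")
  check_prob(repeat_frac, "repeat_frac")
  check_prob(convey_frac, "convey_frac")
  exact <- attendances * hypo_rate * (1 - repeat_frac) * (1 - convey_frac)
  list(exact = exact, rounded = round(exact / 1000) * 1000)
}

#' Severity decrements averaged over time of day
#'
#' The utility decrement applied on recurrence depends on severity and on
#' time of day. For the fortnight-level model the four raw values are
#' collapsed to one decrement per severity by weighting with the proportion
#' of daytime incidents.
#'
#' @param utilities The `utilities` element of a configuration (or a whole
#'   config).
#' @return Named vector `c(ns = ..., s = ...)` of averaged decrements.
#' @export
#' @examples
#' averaged_decrements(default_config()) # ns 0.006, s 0.058 to 3 dp
averaged_decrements <- function(utilities) {
  if (inherits(utilities, "hs2_config")) utilities <- utilities$utilities
  if (isTRUE(utilities$use_alt_decrements)) {
    return(utilities$alt_decrements[c("ns", "s")])
  }
  d <- utilities$decrements
  w <- utilities$day_share
  c(ns = unname(w * d["day_ns"] + (1 - w) * d["night_ns"]),
    s  = unname(w * d["day_s"]  + (1 - w) * d["night_s"]))
}

#' An outcome distribution over (none, non-severe, severe) recurrence
#'
#' Small constructor/validator for the per-fortnight probability distribution
#' of recurrent hypoglycaemia used by the cost-utility analysis.
#'
#' @param p0,p_ns,p_s Probabilities of no recurrence, non-severe recurrence
#'   and severe recurrence; must sum to 1.
#' @return Named numeric vector of class `hs2_outcome_dist`.
#' @export
outcome_dist <- function(p0, p_ns, p_s) {
  x <- c(p0 = p0, p_ns = p_ns, p_s = p_s)
  check_prob(x, "outcome distribution")
  if (abs(sum(x) - 1) > 1e-9) {
    stop("outcome distribution must sum to 1 (got ", sum(x), ")",
         call. = FALSE)
  }
  structure(x, class = "hs2_outcome_dist")
}
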