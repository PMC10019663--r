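#' Default model configuration
#'
#' Returns the complete parameter set of the HS2 economic model as a nested
#' list: the NHS unit-cost schedule (2018-19 price year), the per-state cost
#' assignments with provider attribution, the transition parameters of both
#' arms, utility parameters, probabilistic-sensitivity settings and
#' cost-minimisation settings. Every analysis in the package is a pure
#' function of such a configuration, so alternative scenarios are expressed
#' by editing the returned list (or a YAML serialisation of it, see
#' [load_config()]).
#'
#' Transition parameters follow the model's three patient types in the HS2
#' arm (booklet read and action taken, booklet read only, no actions) and two
#' in the standard-care arm (action taken, no action). Recurrence is governed
#' by per-fortnight incident rates through `1 - exp(-r)`; the severe-recurrence
#' probability applied at each 999/111 severity node is calibrated to the
#' arm's observed repeat EMS-attendance rate (see
#' [calibrate_severity_probability()]).
#'
#' @return A list of class `hs2_config` with elements `cost_schedule`,
#'   `state_costs`, `self_manage`, `transitions`, `utilities`, `population`,
#'   `trial`, `psa` and `costmin`.
#' @export
#' @examples
#' cfg <- default_config()
#' names(cfg)
#' cfg$transitions$hs2$rates
default_config <- function() {
  cfg <- list(
    cost_schedule = list(
      # unit costs in GBP, price year 2018-19
      items = list(
        `111`         = list(cost = 7.33,    unit = "call"),
        `999`         = list(cost = 7.33,    unit = "call"),
        ED1A          = list(cost = 262.57,  unit = "attendance"),
        ED1NA         = list(cost = 170.66,  unit = "attendance"),
        ED2A          = list(cost = 142.26,  unit = "attendance"),
        ED2NA         = list(cost = 109.92,  unit = "attendance"),
        ED3A          = list(cost = 115.69,  unit = "attendance"),
        ED3NA         = list(cost = 73.57,   unit = "attendance"),
        ED4A          = list(cost = 44.17,   unit = "attendance"),
        ED4NA         = list(cost = 45.71,   unit = "attendance"),
        GP            = list(cost = 39.00,   unit = "consultation"),
        HA            = list(cost = 1215.74, unit = "episode"),
        HS2_admin     = list(cost = 2.55,    unit = "minute"),
        HS2_booklet   = list(cost = 1.60,    unit = "booklet"),
        HTR           = list(cost = 47.49,   unit = "patient"),
        STC           = list(cost = 257.34,  unit = "incident"),
        STR           = list(cost = 209.38,  unit = "incident")
      )
    ),
    self_manage = list(
      # proportions over (ED1NA, ED2NA, ED3NA, ED4NA, self-care at zero cost)
      read_action = c(0.08125, 0.08125, 0.01875, 0.01875, 0.800),
      other       = c(0.10625, 0.10625, 0.03125, 0.03125, 0.725)
    ),
    state_costs = list(
      # stage 1
      intervention  = list(cost = 9.95,    provider = "ems"),
      gp_consult    = list(cost = 39.00,   provider = "primary"),
      # stage 2
      call_999      = list(cost = 7.33,    provider = "ems"),
      call_111      = list(cost = 7.33,    provider = "iuc"),
      redirect_999  = list(cost = 7.33,    provider = "iuc"),
      htr           = list(cost = 47.49,   provider = "ems"),
      pathways_111  = list(cost = 71.94,   provider = "iuc"),
      # self-manage costs are derived from the mixes; provider tag only
      self_manage   = list(provider = "secondary"),
      # stage 3
      stc           = list(cost = 257.34,  provider = "ems"),
      str           = list(cost = 209.38,  provider = "ems"),
      ed_ha         = list(cost = 1478.13, provider = "secondary"),
      ed            = list(cost = 168.89,  provider = "secondary")
    ),
    attribution = list(
      # "iuc": the whole 111-pathways disposition cost accrues to IUC;
      # "split": apportioned to secondary/primary care by the relative size
      # of its ED (ED1NA+ED2NA) and primary-care (ED3NA+ED4NA) cost blocks.
      pathways_111 = "iuc"
    ),
    transitions = list(
      hs2 = list(
        stage1 = c(read_action = 0.4125, read_only = 0.3375, no_action = 0.25),
        rates  = c(read_action = 0.75,   read_only = 0.90,   no_action = 1.00),
        p31    = c(read_action = 0.3625, read_only = 0.40,   no_action = 0.40),
        p32    = c(read_action = 0.2375, read_only = 0.35,   no_action = 0.35),
        observed_repeat_rate = 0.045
      ),
      sc = list(
        stage1 = c(action = 0.25, no_action = 0.75),
        rates  = c(action = 0.75, no_action = 1.00),
        p31    = c(action = 0.40, no_action = 0.40),
        p32    = c(action = 0.35, no_action = 0.35),
        observed_repeat_rate = 0.055
      ),
      convey = 0.6,          # P(see-treat-convey | EMS attend)
      admit  = 1 / 3,        # P(hospital admission | conveyed to ED)
      r_max  = 1.65          # upper bound on per-fortnight incident rates
    ),
    utilities = list(
      u0 = 0.8,              # baseline utility; cancels in increments
      decrements = c(day_ns = 0.004, night_ns = 0.007,
                     day_s = 0.062, night_s = 0.057),
      day_share = 0.28,
      annualisation_factor = 9 / 182,
      # recurrence-time distribution within the fortnight (days)
      t_dist = c(min = 0, max = 14, mode = 2),
      # alternative severity decrements (HypoNS, HypoS), off by default
      alt_decrements = c(ns = 0.014, s = 0.047),
      use_alt_decrements = FALSE
    ),
    population = list(
      annual_attendances = 7.9e6,
      hypo_call_rate = 0.006,
      repeat_fraction = 0.05,
      convey_fraction = 0.6
    ),
    trial = list(
      hs2 = c(events = 32, n = 707),
      sc  = c(events = 92, n = 1674),
      day_share = 0.28,
      convey_p = 0.6,
      added_minutes = c(day = 6.6, night = 2.0)
    ),
    psa = list(
      n_sims = 10000,
      rate_support = c(0, 1.65),
      rate_modes = c(r_hs2 = 0.75, r_hs2e = 0.90, r_na = 1.00),
      enforce_rate_ordering = FALSE
    ),
    costmin = list(
      pgp = c(0.3, 0.4, 0.5),
      max_cycles = 6,
      absorption_threshold = 0.95,
      # per-cycle accrual for absorbed patients: nothing beyond the
      # once-only GP fee ("none", the default) or the arm's GP-engaged
      # patient type's recurrence-management expectation ("gp_type")
      absorbed_accrual = "none",
      n_sims = 10000
    )
  )
  structure(cfg, class = "hs2_config")
}

#' @export
print.hs2_config <- function(x, ...) {
  cat("<hs2_config>\n")
  cat("  cost schedule items :", length(x$cost_schedule$items), "\n")
  cat("  HS2 stage-1 probs   :",
      paste(sprintf("%s=%.4f", names(x$transitions$hs2$stage1),
                    x$transitions$hs2$stage1), collapse = ", "), "\n")
  cat("  SC stage-1 probs    :",
      paste(sprintf("%s=%.4f", names(x$transitions$sc$stage1),
                    x$transitions$sc$stage1), collapse = ", "), "\n")
  cat("  incident rates (HS2):",
      paste(sprintf("%.2f", x$transitions$hs2$rates), collapse = ", "),
      "per fortnight\n")
  cat("  observed repeat rate: HS2",
      x$transitions$hs2$observed_repeat_rate, "/ SC",
      x$transitions$sc$observed_repeat_rate, "\n")
  invisible(x)
}

#' Look up a unit cost in the cost schedule
#'
#' @param schedule The `cost_schedule` element of an [default_config()] list
#'   (or a whole config).
#' @param code Item code, e.g. `"STR"`, `"999"`, `"ED1NA"`.
#' @return Unit cost in GBP.
#' @export
unit_cost <- function(schedule, code) {
  if (inherits(schedule, "hs2_config")) schedule <- schedule$cost_schedule
  item <- schedule$items[[code]]
  if (is.null(item)) {
    stop("unknown cost-schedule code: ", code, call. = FALSE)
  }
  item$cost
}

required_schedule_codes <- function() {
  c("111", "999", "ED1A", "ED1NA", "ED2A", "ED2NA", "ED3A", "ED3NA",
    "ED4A", "ED4NA", "GP", "HA", "HS2_admin", "HS2_booklet",
    "HTR", "STC", "STR")
}

check_prob <- function(p, what, max = 1) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > max)) {
    stop(what, " must lie in [0, ", max, "]; got ",
         paste(signif(p, 6), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the parameter set: presence of all
#' cost-schedule codes, non-negative costs, probabilities in \[0, 1\],
#' stage-1 probabilities summing to at most 1 per arm (the residual is the
#' final patient type), self-manage mixes summing to 1, rate bounds, and
#' utility decrements in (0, 1).
#'
#' @param config A configuration list as returned by [default_config()] or
#'   [load_config()].
#' @return The configuration, invisibly, if valid; otherwise an error naming
#'   the offending key.
#' @export
validate_config <- function(config) {
  codes <- names(config$cost_schedule$items)
  missing <- setdiff(required_schedule_codes(), codes)
  if (length(missing)) {
    stop("cost schedule is missing codes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  costs <- vapply(config$cost_schedule$items, function(i) i$cost, numeric(1))
  if (any(!is.finite(costs)) || any(costs < 0)) {
    stop("all cost-schedule unit costs must be finite and >= 0",
         call. = FALSE)
  }

  for (mix_name in c("read_action", "other")) {
    mix <- config$self_manage[[mix_name]]
    if (length(mix) != 5L) {
      stop("self_manage$", mix_name, " must have 5 proportions",
           call. = FALSE)
    }
    check_prob(mix, paste0("self_manage$", mix_name))
    if (abs(sum(mix) - 1) > 1e-9) {
      stop("self_manage$", mix_name, " must sum to 1 (got ",
           sum(mix), ")", call. = FALSE)
    }
  }

  for (arm in c("hs2", "sc")) {
    tr <- config$transitions[[arm]]
    check_prob(tr$stage1, paste0("transitions$", arm, "$stage1"))
    if (sum(tr$stage1) > 1 + 1e-9) {
      stop("transitions$", arm, "$stage1 must sum to at most 1",
           call. = FALSE)
    }
    if (any(tr$rates < 0) || any(tr$rates >= config$transitions$r_max)) {
      stop("transitions$", arm, "$rates must lie in [0, r_max)",
           call. = FALSE)
    }
    check_prob(tr$p31, paste0("transitions$", arm, "$p31"))
    check_prob(tr$p32, paste0("transitions$", arm, "$p32"))
    if (any(tr$p31 + tr$p32 > 1 + 1e-9)) {
      stop("transitions$", arm,
           ": p31 + p32 must be at most 1 per patient type (the residual ",
           "is self-management)", call. = FALSE)
    }
    check_prob(tr$observed_repeat_rate,
               paste0("transitions$", arm, "$observed_repeat_rate"))
  }
  check_prob(config$transitions$convey, "transitions$convey")
  check_prob(config$transitions$admit, "transitions$admit")

  ut <- config$utilities
  check_prob(ut$u0, "utilities$u0")
  if (any(ut$decrements <= 0) || any(ut$decrements >= 1)) {
    stop("utilities$decrements must lie strictly in (0, 1)", call. = FALSE)
  }
  check_prob(ut$day_share, "utilities$day_share")
  td <- ut$t_dist
  if (!(td["min"] <= td["mode"] && td["mode"] <= td["max"])) {
    stop("utilities$t_dist mode must lie within its support", call. = FALSE)
  }

  check_prob(config$costmin$pgp, "costmin$pgp")
  if (!config$costmin$absorbed_accrual %in% c("gp_type", "none")) {
    stop("costmin$absorbed_accrual must be \"gp_type\" or \"none\"",
         call. = FALSE)
  }
  if (!config$attribution$pathways_111 %in% c("iuc", "split")) {
    stop("attribution$pathways_111 must be \"iuc\" or \"split\"",
         call. = FALSE)
  }
  invisible(config)
}

#' Read and write configurations as YAML
#'
#' `write_config()` serialises a configuration to a human-editable YAML file
#' mirroring the parameter tables field for field; `load_config()` reads one
#' back, restores the numeric vector structure and validates it. A
#' write/load round trip reproduces the parameter set exactly.
#'
#' @param config A configuration list.
#' @param path Path of the YAML file.
#' @return `load_config()` returns a validated `hs2_config` list;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

#' @rdname write_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  # yaml drops names on scalars and reads named vectors as lists; coerce the
  # known numeric-vector leaves back, everything else is taken as parsed
  restore <- function(template, value) {
    if (is.list(template) && !is.null(names(template))) {
      for (nm in names(template)) {
        if (!is.null(value[[nm]])) {
          template[[nm]] <- restore(template[[nm]], value[[nm]])
        }
      }
      template
    } else if (is.numeric(template) && length(template) > 1L) {
      out <- unlist(value)
      stats::setNames(as.numeric(out), names(template))
    } else if (is.list(value)) {
      unlist(value)
    } else {
      value
    }
  }
  out <- restore(unclass(cfg), raw)
  out <- structure(out, class = "hs2_config")
  validate_config(out)
  out
}
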