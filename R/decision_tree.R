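PROVIDERS <- c("ems", "iuc", "primary", "secondary")

provider_vec <- function(cost, provider) {
  v <- stats::setNames(numeric(4), PROVIDERS)
  v[provider] <- cost
  v
}

# Resolve every state cost of the model into provider-attributed vectors.
# Self-manage costs are constructed from the outcome mixes and the unit-cost
# schedule; the 111-pathways disposition cost is attributed per the
# `attribution$pathways_111` switch.
model_cost_pieces <- function(config) {
  sc <- config$state_costs
  pw111_cost <- sc$pathways_111$cost
  if (config$attribution$pathways_111 == "split") {
    ed_block <- unit_cost(config, "ED1NA") + unit_cost(config, "ED2NA")
    pc_block <- unit_cost(config, "ED3NA") + unit_cost(config, "ED4NA")
    pw111 <- provider_vec(pw111_cost * ed_block / (ed_block + pc_block),
                          "secondary") +
      provider_vec(pw111_cost * pc_block / (ed_block + pc_block), "primary")
  } else {
    pw111 <- provider_vec(pw111_cost, sc$pathways_111$provider)
  }
  list(
    intervention = provider_vec(sc$intervention$cost, sc$intervention$provider),
    gp       = provider_vec(sc$gp_consult$cost, sc$gp_consult$provider),
    call999  = provider_vec(sc$call_999$cost, sc$call_999$provider),
    call111  = provider_vec(sc$call_111$cost, sc$call_111$provider),
    redirect = provider_vec(sc$redirect_999$cost, sc$redirect_999$provider),
    htr      = provider_vec(sc$htr$cost, sc$htr$provider),
    pw111    = pw111,
    stc      = provider_vec(sc$stc$cost, sc$stc$provider),
    str      = provider_vec(sc$str$cost, sc$str$provider),
    ed_ha    = provider_vec(sc$ed_ha$cost, sc$ed_ha$provider),
    ed       = provider_vec(sc$ed$cost, sc$ed$provider),
    sm_read_action = provider_vec(
      self_manage_cost(config$self_manage$read_action, config),
      sc$self_manage$provider),
    sm_other = provider_vec(
      self_manage_cost(config$self_manage$other, config),
      sc$self_manage$provider)
  )
}

# Per-patient-type parameters of one arm: stage-1 probability and cost,
# incident rate, 999/111 call probabilities and self-manage cost variant.
arm_spec <- function(arm, config) {
  arm <- match.arg(arm, c("hs2", "sc"))
  pieces <- model_cost_pieces(config)
  tr <- config$transitions[[arm]]
  types <- names(tr$stage1)
  spec <- lapply(types, function(ty) {
    stage1_cost <- numeric(4)
    names(stage1_cost) <- PROVIDERS
    if (arm == "hs2") stage1_cost <- stage1_cost + pieces$intervention
    if (ty %in% c("read_action", "action")) {
      stage1_cost <- stage1_cost + pieces$gp
    }
    sm <- if (arm == "hs2" && ty == "read_action") {
      pieces$sm_read_action
    } else {
      pieces$sm_other
    }
    list(type = ty,
         stage1_prob = unname(tr$stage1[ty]),
         stage1_cost = stage1_cost,
         rate = unname(tr$rates[ty]),
         p31 = unname(tr$p31[ty]),
         p32 = unname(tr$p32[ty]),
         sm_cost = sm)
  })
  names(spec) <- types
  list(arm = arm, types = spec, pieces = pieces,
       convey = config$transitions$convey,
       admit = config$transitions$admit,
       observed_rate = tr$observed_repeat_rate)
}

#' Sum of severe-recurrence pathway contributions
#'
#' The calibration denominator: the sum over patient types of
#' stage-1 probability x recurrence probability x total call probability
#' (999 plus 111). Multiplying it by the arm's constant severity probability
#' gives the arm's total probability of repeat EMS attendance.
#'
#' @param arm `"hs2"` or `"sc"`.
#' @param config Model configuration.
#' @return A single probability.
#' @export
#' @examples
#' severity_pathway_sum("hs2") # 0.3993
severity_pathway_sum <- function(arm, config = default_config()) {
  spec <- arm_spec(arm, config)
  sum(vapply(spec$types, function(ty) {
    ty$stage1_prob * rate_to_probability(ty$rate) * (ty$p31 + ty$p32)
  }, numeric(1)))
}

#' Calibrate the severity/attendance probability to an observed repeat rate
#'
#' EMS clinicians attend only severe recurrences, so the arm's probability of
#' repeat EMS attendance equals the severity probability (assumed constant
#' across the arm's 999 and 111 severity nodes) times the sum of pathway
#' contributions in which an attendance can occur. Tethering that product to
#' the repeat-attendance rate observed in the trial gives
#' `p4 = observed_rate / severity_pathway_sum(arm)`.
#'
#' @param observed_rate Observed repeat EMS-attendance proportion in \[0, 1\].
#' @param arm `"hs2"` or `"sc"`, or an object returned by [build_arm()].
#' @param config Model configuration (ignored when `arm` is a built arm).
#' @return The calibrated severity probability.
#' @export
#' @examples
#' calibrate_severity_probability(0.045, "hs2") # 0.113 to 3 dp
#' calibrate_severity_probability(0.055, "sc")  # 0.121 to 3 dp
calibrate_severity_probability <- function(observed_rate, arm,
                                           config = default_config()) {
  check_prob(observed_rate, "observed_rate")
  sigma <- if (inherits(arm, "hs2_arm")) {
    attr(arm, "sigma_pi")
  } else {
    severity_pathway_sum(arm, config)
  }
  if (sigma <= 0) {
    if (observed_rate == 0) return(0)
    stop("degenerate model: no pathway can produce an EMS attendance",
         call. = FALSE)
  }
  p4 <- observed_rate / sigma
  if (p4 > 1) {
    stop("calibration infeasible: observed rate ", observed_rate,
         " exceeds the maximum attainable attendance probability ",
         signif(sigma, 6), call. = FALSE)
  }
  p4
}

# Enumerate the ten terminal pathways of one patient type. Stage 3 (see,
# treat and convey to ED with possible admission, or discharge at scene) is
# mapped onto both severity nodes; EMS attendance occurs only for severe
# recurrence, which fixes the outcome label.
type_pathways <- function(ty, spec, p4) {
  p <- spec$pieces
  p5 <- spec$convey
  p6 <- spec$admit
  p2 <- rate_to_probability(ty$rate)
  s1 <- ty$stage1_prob
  resid <- 1 - ty$p31 - ty$p32
  base <- ty$stage1_cost

  row <- function(states, prob, cost, outcome, ems_attend) {
    list(states = states, probability = prob, cost = cost,
         outcome = outcome, ems_attend = ems_attend)
  }
  stage3 <- function(prefix, prob, cost) {
    list(
      row(paste0(prefix, " > EMS attend > STC > ED+HA"), prob * p5 * p6,
          cost + p$stc + p$ed_ha, "HypoS", TRUE),
      row(paste0(prefix, " > EMS attend > STC > ED"), prob * p5 * (1 - p6),
          cost + p$stc + p$ed, "HypoS", TRUE),
      row(paste0(prefix, " > EMS attend > STR"), prob * (1 - p5),
          cost + p$str, "HypoS", TRUE)
    )
  }

  out <- list(
    row("no repeat", s1 * (1 - p2), base, "none", FALSE)
  )
  # 999 channel
  out <- c(out,
    stage3("repeat > call 999 > HypoS", s1 * p2 * ty$p31 * p4,
           base + p$call999),
    list(row("repeat > call 999 > HypoNS > HTR",
             s1 * p2 * ty$p31 * (1 - p4),
             base + p$call999 + p$htr, "HypoNS", FALSE)),
    # 111 channel: severe cases are redirected to 999 before EMS attends
    stage3("repeat > call 111 > HypoS > redirect 999",
           s1 * p2 * ty$p32 * p4,
           base + p$call111 + p$redirect),
    list(row("repeat > call 111 > HypoNS > 111 pathways",
             s1 * p2 * ty$p32 * (1 - p4),
             base + p$call111 + p$pw111, "HypoNS", FALSE)),
    list(row("repeat > self-manage", s1 * p2 * resid,
             base + ty$sm_cost, "HypoNS", FALSE))
  )
  out
}

#' Build the decision-tree model of one arm
#'
#' Enumerates every terminal pathway of the arm: for each patient type, one
#' no-recurrence pathway, four via a 999 call (severe recurrence attended by
#' EMS then see-treat-convey with or without admission or see-treat-refer;
#' non-severe resolved remotely), four via a 111 call (severe redirected to
#' 999 then the same three attendance outcomes; non-severe handled through
#' 111 dispositions) and one self-managed pathway. The HS2 arm has three
#' patient types and 30 pathways (18 with an EMS attendance); standard care
#' has two types and 20 pathways (12 with an attendance).
#'
#' @param arm `"hs2"` or `"sc"`.
#' @param config Model configuration.
#' @param p4 Severity/attendance probability applied at every severity node.
#'   By default it is calibrated to the arm's configured observed
#'   repeat-attendance rate.
#' @return A tibble of class `hs2_arm`, one row per pathway, with the state
#'   sequence, probability, provider-attributed costs, total cost, outcome
#'   label and an EMS-attendance flag. Attributes carry the arm name, the
#'   severity probability and the calibration denominator.
#' @export
#' @examples
#' arm <- build_arm("hs2")
#' nrow(arm)                 # 30
#' sum(arm$probability)      # 1
build_arm <- function(arm, config = default_config(), p4 = NULL) {
  spec <- arm_spec(arm, config)
  if (is.null(p4)) {
    p4 <- calibrate_severity_probability(spec$observed_rate, arm, config)
  }
  check_prob(p4, "p4")
  rows <- list()
  for (ty in spec$types) {
    for (pw in type_pathways(ty, spec, p4)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        arm = spec$arm,
        patient_type = ty$type,
        states = pw$states,
        probability = pw$probability,
        cost_ems = pw$cost[["ems"]],
        cost_iuc = pw$cost[["iuc"]],
        cost_primary = pw$cost[["primary"]],
        cost_secondary = pw$cost[["secondary"]],
        cost_total = sum(pw$cost),
        outcome = pw$outcome,
        ems_attend = pw$ems_attend
      )
    }
  }
  out <- do.call(rbind, rows)
  structure(out,
            class = c("hs2_arm", class(out)),
            arm = spec$arm,
            p4 = p4,
            sigma_pi = severity_pathway_sum(arm, config),
            observed_rate = spec$observed_rate)
}

#' @export
print.hs2_arm <- function(x, ...) {
  cat(sprintf("<hs2_arm: %s> %d pathways (%d with EMS attendance), p4 = %.4f\n",
              attr(x, "arm"), nrow(x), sum(x$ems_attend), attr(x, "p4")))
  NextMethod()
}

#' Per-fortnight outcome distribution of an arm
#'
#' Aggregates pathway probabilities into the distribution over no recurrence,
#' non-severe recurrence and severe recurrence. By calibration, the severe
#' probability equals the arm's observed repeat-attendance rate.
#'
#' @param arm_model An [build_arm()] result.
#' @return An `hs2_outcome_dist` vector `(p0, p_ns, p_s)`.
#' @export
#' @examples
#' outcome_distribution(build_arm("hs2")) # (0.424, 0.531, 0.045)
outcome_distribution <- function(arm_model) {
  stopifnot(inherits(arm_model, "hs2_arm"))
  p0 <- sum(arm_model$probability[arm_model$outcome == "none"])
  p_s <- sum(arm_model$probability[arm_model$outcome == "HypoS"])
  outcome_dist(p0, 1 - p0 - p_s, p_s)
}

#' Expected per-patient cost of an arm, by service provider
#'
#' Probability-weighted sum of pathway costs, reported for each provider
#' (EMS, IUC, primary care, secondary care) and in total. The total equals
#' the sum of the provider components by construction.
#'
#' @param arm_model An [build_arm()] result.
#' @return A tibble with one row per provider plus a `total` row, columns
#'   `provider` and `cost`.
#' @export
expected_costs <- function(arm_model) {
  stopifnot(inherits(arm_model, "hs2_arm"))
  pr <- arm_model$probability
  cost <- c(
    ems = sum(pr * arm_model$cost_ems),
    iuc = sum(pr * arm_model$cost_iuc),
    primary = sum(pr * arm_model$cost_primary),
    secondary = sum(pr * arm_model$cost_secondary)
  )
  tibble::tibble(provider = c(PROVIDERS, "total"),
                 cost = unname(c(cost, sum(cost))))
}

#' Expected cost conditional on patient type
#'
#' The expected NHS cost of managing a patient of each type: the type's
#' stage-1 cost plus its recurrence-management expectation.
#'
#' @param arm_model An [build_arm()] result.
#' @return A tibble with `patient_type`, `stage1_prob` and `cost` columns.
#' @export
patient_type_costs <- function(arm_model) {
  stopifnot(inherits(arm_model, "hs2_arm"))
  types <- unique(arm_model$patient_type)
  rows <- lapply(types, function(ty) {
    sub <- arm_model[arm_model$patient_type == ty, ]
    s1 <- sum(sub$probability)
    tibble::tibble(patient_type = ty, stage1_prob = s1,
                   cost = sum(sub$probability * sub$cost_total) / s1)
  })
  do.call(rbind, rows)
}

# ---- independent recursive evaluator ------------------------------------

tree_leaf <- function(cost, outcome) {
  list(cost = cost, outcome = outcome, children = NULL)
}
tree_node <- function(cost, probs, children) {
  list(cost = cost, outcome = NULL, probs = probs, children = children)
}

# Nested-list representation of the arm's full tree, composed stage by stage.
build_tree <- function(arm, config = default_config(), p4 = NULL) {
  spec <- arm_spec(arm, config)
  if (is.null(p4)) {
    p4 <- calibrate_severity_probability(spec$observed_rate, arm, config)
  }
  p <- spec$pieces
  p5 <- spec$convey
  p6 <- spec$admit
  zero <- stats::setNames(numeric(4), PROVIDERS)

  stage3 <- function(entry_cost) {
    tree_node(entry_cost, c(p5 * p6, p5 * (1 - p6), 1 - p5), list(
      tree_leaf(p$stc + p$ed_ha, "HypoS"),
      tree_leaf(p$stc + p$ed, "HypoS"),
      tree_leaf(p$str, "HypoS")
    ))
  }
  type_node <- function(ty) {
    p2 <- rate_to_probability(ty$rate)
    recurrence <- tree_node(zero, c(ty$p31, ty$p32, 1 - ty$p31 - ty$p32), list(
      tree_node(p$call999, c(p4, 1 - p4), list(
        stage3(zero),
        tree_leaf(p$htr, "HypoNS")
      )),
      tree_node(p$call111, c(p4, 1 - p4), list(
        stage3(p$redirect),
        tree_leaf(p$pw111, "HypoNS")
      )),
      tree_leaf(ty$sm_cost, "HypoNS")
    ))
    tree_node(ty$stage1_cost, c(1 - p2, p2), list(
      tree_leaf(zero, "none"),
      recurrence
    ))
  }
  probs <- vapply(spec$types, function(ty) ty$stage1_prob, numeric(1))
  tree_node(zero, unname(probs), lapply(spec$types, type_node))
}

# Expected provider costs and outcome distribution by depth-first recursion;
# the cross-check for the flat pathway enumeration.
evaluate_tree <- function(node) {
  outcomes <- c(none = 0, HypoNS = 0, HypoS = 0)
  if (is.null(node$children)) {
    outcomes[node$outcome] <- 1
    return(list(cost = node$cost, outcomes = outcomes))
  }
  cost <- node$cost
  for (i in seq_along(node$children)) {
    child <- evaluate_tree(node$children[[i]])
    cost <- cost + node$probs[i] * child$cost
    outcomes <- outcomes + node$probs[i] * child$outcomes
  }
  list(cost = cost, outcomes = outcomes)
}

#' Recursive expected-value evaluation of an arm
#'
#' Evaluates the arm's tree by depth-first recursion over a nested node
#' structure rather than by enumerating terminal pathways. Used as an
#' independent cross-check of [build_arm()] + [expected_costs()]: both
#' evaluators must agree to numerical precision.
#'
#' @inheritParams build_arm
#' @return A list with `cost` (named provider vector, GBP per patient),
#'   `total`, and `outcomes` (probabilities of none/HypoNS/HypoS).
#' @export
evaluate_arm_recursive <- function(arm, config = default_config(), p4 = NULL) {
  res <- evaluate_tree(build_tree(arm, config, p4))
  list(cost = res$cost, total = sum(res$cost), outcomes = res$outcomes)
}

#' Export the pathway audit table
#'
#' Writes one CSV row per pathway of both arms: arm, patient type, state
#' sequence, probability, provider-attributed costs and outcome label. This
#' is the audit artefact for the whole model.
#'
#' @param config Model configuration.
#' @param path Output CSV path.
#' @return The combined pathway tibble, invisibly.
#' @export
write_pathways <- function(config = default_config(), path) {
  both <- rbind(
    tibble::as_tibble(build_arm("hs2", config)),
    tibble::as_tibble(build_arm("sc", config))
  )
  utils::write.csv(both, path, row.names = FALSE)
  invisible(both)
}
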