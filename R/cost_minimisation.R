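# Per-arm cycle cost accumulation for the absorbing-chain cost-minimisation
# model. `ev` is an arm_evaluate() result (possibly over many draws). The
# first patient type of each arm (booklet read + action taken / action
# taken) starts absorbed: it has already engaged with its GP in cycle 1.
# Later cycles move transient mass to absorption with probability `pgp`
# (incurring the once-only GP fee), accrue each surviving type's first-cycle
# recurrence-management expectation on its remaining mass and, under the
# "gp_type" accrual rule, accrue the GP-engaged type's expectation on the
# absorbed mass.
chain_costs <- function(ev, gp_cost, pgp, max_cycles,
                        accrual = c("gp_type", "none")) {
  accrual <- match.arg(accrual)
  s1 <- ev$type_stage1_prob
  k <- length(s1)
  n <- ev$n
  absorbed_idx <- 1L
  transient_idx <- setdiff(seq_len(k), absorbed_idx)
  accrual_cost <- if (accrual == "gp_type") {
    ev$type_continuation[, absorbed_idx]
  } else {
    numeric(n)
  }

  cost <- matrix(NA_real_, n, max_cycles)
  absorbed <- numeric(max_cycles)
  cost[, 1L] <- ev$total
  m <- s1[transient_idx]                     # transient mass, draw-invariant
  a <- s1[absorbed_idx]
  absorbed[1L] <- a
  for (cy in seq_len(max_cycles)[-1L]) {
    new_abs <- pgp * sum(m)
    m <- m * (1 - pgp)
    a <- a + new_abs
    cont <- ev$type_continuation[, transient_idx, drop = FALSE] %*% m
    cost[, cy] <- gp_cost * new_abs + drop(cont) + a * accrual_cost
    absorbed[cy] <- a
  }
  list(cost = cost, absorbed = absorbed)
}

#' Run the cost-minimisation chains at baseline parameters
#'
#' Fortnight-length cycles: cycle 1 is the full economic model of both arms
#' (including intervention and stage-1 costs); in every later cycle patients
#' who have not yet consulted their GP do so with probability `pgp`
#' (incurring the GP fee once and entering the absorbing state) or remain
#' exposed and accrue their patient type's first-cycle recurrence-management
#' cost. Cumulative costs per arm are recorded along with the cycles at
#' which the HS2 arm's accumulation is strictly below standard care's.
#' Recording stops (and the iteration with it) at the first cycle where the
#' absorbed fraction exceeds the configured threshold in both arms, or at
#' `max_cycles`.
#'
#' @param config Model configuration.
#' @param pgp Per-cycle GP-consultation (absorption) probability in \[0, 1\].
#' @param max_cycles Maximum number of fortnightly cycles.
#' @return A tibble of class `hs2_chain`: `cycle`, per-arm cycle and
#'   cumulative costs, per-arm absorbed fractions, `crossing` (HS2
#'   cumulative cost strictly below standard care) and `recorded` (FALSE
#'   once absorption has exceeded the threshold in both arms).
#' @export
#' @examples
#' run_chain(pgp = 0.4)
run_chain <- function(config = default_config(), pgp,
                      max_cycles = config$costmin$max_cycles) {
  check_prob(pgp, "pgp")
  validate_config(config)
  gp_cost <- config$state_costs$gp_consult$cost
  accrual <- config$costmin$absorbed_accrual
  thr <- config$costmin$absorption_threshold
  ch_h <- chain_costs(arm_evaluate("hs2", config), gp_cost, pgp, max_cycles,
                      accrual)
  ch_s <- chain_costs(arm_evaluate("sc", config), gp_cost, pgp, max_cycles,
                      accrual)
  both_absorbed <- ch_h$absorbed > thr & ch_s$absorbed > thr
  # recording stops at the first cycle where both arms exceed the threshold
  recorded <- cumsum(both_absorbed) == 0
  keep <- seq_len(if (any(both_absorbed)) which(both_absorbed)[1] else max_cycles)
  cum_h <- cumsum(ch_h$cost[1, ])
  cum_s <- cumsum(ch_s$cost[1, ])
  out <- tibble::tibble(
    cycle = keep,
    cost_hs2 = ch_h$cost[1, keep],
    cost_sc = ch_s$cost[1, keep],
    cum_hs2 = cum_h[keep],
    cum_sc = cum_s[keep],
    absorbed_hs2 = ch_h$absorbed[keep],
    absorbed_sc = ch_s$absorbed[keep],
    recorded = recorded[keep]
  )
  out$crossing <- out$recorded & out$cum_hs2 < out$cum_sc
  structure(out, class = c("hs2_chain", class(out)))
}

#' Probability that the intervention is least-cost, by cycle
#'
#' Over `n_sims` first-cycle parameter draws (the same sampling scheme as
#' [run_psa()]: triangular incident rates, binomial repeat-attendance rates,
#' per-draw recalibration), runs the cost-minimisation chains for each GP
#' consultation rate and estimates, for each completed cycle, the proportion
#' of draws in which the HS2 arm's cumulative cost has fallen strictly below
#' standard care's at or before that cycle. First-cycle conditions replicate
#' in later cycles; stochasticity enters only through the first-cycle draw.
#'
#' @param config Model configuration.
#' @param pgp Vector of absorption probabilities.
#' @param n_sims Number of simulations.
#' @param seed Optional integer seed.
#' @param report_cycles Number of completed cycles to report.
#' @return A list of class `hs2_costmin`: `by_pgp` (tibble `pgp`, `cycle`,
#'   `proportion`), `average` (tibble `cycle`, `proportion` averaged across
#'   the `pgp` values), `n_excluded` and `seed`.
#' @export
estimate_least_cost_probability <- function(config = default_config(),
                                            pgp = config$costmin$pgp,
                                            n_sims = config$costmin$n_sims,
                                            seed = NULL,
                                            report_cycles = 5L) {
  check_prob(pgp, "pgp")
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  max_cycles <- max(config$costmin$max_cycles, report_cycles)
  gp_cost <- config$state_costs$gp_consult$cost
  accrual <- config$costmin$absorbed_accrual
  thr <- config$costmin$absorption_threshold

  draws <- sample_draws(n_sims, config)
  rm <- draw_rate_matrices(draws)
  ev_h <- arm_evaluate("hs2", config, rates = rm$hs2,
                       observed_rate = draws$rate_hs2)
  ev_s <- arm_evaluate("sc", config, rates = rm$sc,
                       observed_rate = draws$rate_sc)
  ok <- ev_h$feasible & ev_s$feasible

  subset_ev <- function(ev) {
    ev$total <- ev$total[ok]
    ev$type_continuation <- ev$type_continuation[ok, , drop = FALSE]
    ev$n <- sum(ok)
    ev
  }
  ev_h <- subset_ev(ev_h)
  ev_s <- subset_ev(ev_s)

  rows <- lapply(pgp, function(pg) {
    ch_h <- chain_costs(ev_h, gp_cost, pg, max_cycles, accrual)
    ch_s <- chain_costs(ev_s, gp_cost, pg, max_cycles, accrual)
    both_absorbed <- ch_h$absorbed > thr & ch_s$absorbed > thr
    recorded <- cumsum(both_absorbed) == 0
    cum_h <- t(apply(ch_h$cost, 1, cumsum))
    cum_s <- t(apply(ch_s$cost, 1, cumsum))
    crossed <- matrix(FALSE, nrow(cum_h), max_cycles)
    for (cy in seq_len(max_cycles)) {
      now <- recorded[cy] & cum_h[, cy] < cum_s[, cy]
      crossed[, cy] <- if (cy == 1L) now else crossed[, cy - 1L] | now
    }
    tibble::tibble(
      pgp = pg,
      cycle = seq_len(report_cycles),
      proportion = colMeans(crossed)[seq_len(report_cycles)]
    )
  })
  by_pgp <- do.call(rbind, rows)
  avg <- stats::aggregate(proportion ~ cycle, data = by_pgp, FUN = mean)
  structure(list(
    by_pgp = by_pgp,
    average = tibble::as_tibble(avg),
    n_sims = n_sims,
    n_excluded = sum(!ok),
    seed = seed
  ), class = "hs2_costmin")
}

#' @export
print.hs2_costmin <- function(x, ...) {
  cat(sprintf("Cost-minimisation analysis: %d simulations (%d excluded)\n",
              x$n_sims, x$n_excluded))
  cat("  P(HS2 least total cost) by completed cycle, averaged over pGP:\n")
  cat(sprintf("    cycle %d: %.1f%%\n", x$average$cycle,
              100 * x$average$proportion), sep = "")
  invisible(x)
}
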