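#' Expected days of utility decrement within the fortnight
#'
#' If hypoglycaemia recurs at day `T` of the 14-day window the utility
#' decrement applies from `T` to the end of the window, with no recovery
#' inside the window, i.e. for `14 - T` days. With `T` triangular on
#' (0, 14) days with mode 2, the closed-form expectation is
#' `14 - (0 + 14 + 2)/3 = 26/3` days.
#'
#' @param t_dist Named vector `c(min, max, mode)` in days.
#' @return Expected number of decrement days.
#' @export
expected_decrement_days <- function(t_dist = default_config()$utilities$t_dist) {
  unname(t_dist["max"] - (t_dist["min"] + t_dist["max"] + t_dist["mode"]) / 3)
}

as_outcome_dist <- function(x) {
  if (inherits(x, "hs2_outcome_dist")) return(x)
  outcome_dist(x[["p0"]], x[["p_ns"]], x[["p_s"]])
}

#' Annualised QALY difference between the two arms
#'
#' The utility pathway is constant at the baseline utility unless
#' hypoglycaemia recurs, at which point it drops by a severity-specific
#' decrement for the remainder of the fortnight. The difference in the
#' annualised area under the two arms' expected utility pathways is linear in
#' the day-share-averaged decrements:
#' `factor * (d_ns * (pNS_comp - pNS_int) + d_s * (pS_comp - pS_int))`,
#' where the expectation over the recurrence time `T` is folded into the
#' annualisation factor. The baseline utility cancels in the difference.
#'
#' `method = "mc"` instead draws `T` from its triangular distribution and
#' weights each draw by its decrement duration relative to the closed-form
#' expectation; it converges to the closed form and serves as its
#' integration cross-check.
#'
#' @param dist_comp,dist_int Outcome distributions (comparator and
#'   intervention), as returned by [outcome_distribution()].
#' @param utilities The `utilities` element of a configuration (or a whole
#'   config).
#' @param method `"closed_form"` (default) or `"mc"`.
#' @param n_draws Number of Monte-Carlo draws of `T` for `method = "mc"`.
#' @return QALY difference per patient per year (positive favours the
#'   intervention).
#' @export
#' @examples
#' cfg <- default_config()
#' d_sc <- outcome_dist(0.394, 0.551, 0.055)
#' d_hs2 <- outcome_dist(0.424, 0.531, 0.045)
#' qaly_difference(d_sc, d_hs2, cfg) # about 3.46e-5
qaly_difference <- function(dist_comp, dist_int,
                            utilities = default_config(),
                            method = c("closed_form", "mc"),
                            n_draws = 1e6) {
  method <- match.arg(method)
  dist_comp <- as_outcome_dist(dist_comp)
  dist_int <- as_outcome_dist(dist_int)
  if (inherits(utilities, "hs2_config")) utilities <- utilities$utilities
  dec <- averaged_decrements(utilities)
  base <- dec[["ns"]] * (dist_comp[["p_ns"]] - dist_int[["p_ns"]]) +
    dec[["s"]] * (dist_comp[["p_s"]] - dist_int[["p_s"]])
  f <- utilities$annualisation_factor
  if (method == "closed_form") {
    return(f * base)
  }
  td <- utilities$t_dist
  t_draw <- rtriangular(n_draws, td[["min"]], td[["max"]], td[["mode"]])
  weight <- (td[["max"]] - t_draw) / expected_decrement_days(td)
  f * mean(weight) * base
}

#' Cost per QALY
#'
#' Divides the incremental cost by the annualised QALY difference. Reported
#' at full precision with a 2-significant-figure companion value for
#' headline reporting.
#'
#' @param delta_cost Incremental cost (GBP per patient).
#' @param qaly_diff QALY difference per patient per year.
#' @return A list with `value`, `value_2sf`, `defined`.
#' @export
#' @examples
#' cost_per_qaly(9.29, 3.462e-5)$value_2sf # 270000
cost_per_qaly <- function(delta_cost, qaly_diff) {
  if (qaly_diff == 0) {
    return(list(value = NA_real_, value_2sf = NA_real_, defined = FALSE))
  }
  v <- delta_cost / qaly_diff
  list(value = v, value_2sf = signif(v, 2), defined = TRUE)
}

#' Cost-utility analysis
#'
#' Runs the calibrated baseline model, computes the annualised QALY
#' difference from the two arms' outcome distributions and divides the
#' incremental cost by it.
#'
#' @param config Model configuration.
#' @return A list of class `hs2_cua` with the outcome distributions, the
#'   averaged decrements, the annualisation factor, `qaly_diff`,
#'   `delta_cost` and `icer` (the [cost_per_qaly()] list).
#' @export
run_cost_utility <- function(config = default_config()) {
  base <- run_baseline(config)
  qd <- qaly_difference(base$outcome_sc, base$outcome_hs2, config)
  structure(list(
    outcome_hs2 = base$outcome_hs2,
    outcome_sc = base$outcome_sc,
    decrements = averaged_decrements(config),
    annualisation_factor = config$utilities$annualisation_factor,
    qaly_diff = qd,
    delta_cost = base$delta_cost,
    icer = cost_per_qaly(base$delta_cost, qd)
  ), class = "hs2_cua")
}

#' @export
print.hs2_cua <- function(x, ...) {
  cat("Cost-utility analysis\n")
  cat(sprintf("  QALY difference: %.4g per patient per year\n", x$qaly_diff))
  cat(sprintf("  incremental cost: £%.2f\n", x$delta_cost))
  if (x$icer$defined) {
    cat(sprintf("  ICER: £%s/QALY (2 sf: £%s)\n",
                format(round(x$icer$value), big.mark = ","),
                format(x$icer$value_2sf, big.mark = ",")))
  }
  invisible(x)
}
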