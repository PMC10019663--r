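#' Triangular random deviates
#'
#' Inverse-CDF sampling from the triangular distribution on `(min, max)`
#' with the given mode.
#'
#' @param n Number of draws.
#' @param min,max Support bounds, `min < max`.
#' @param mode Mode, inside the support.
#' @return Numeric vector of draws.
#' @export
#' @examples
#' mean(rtriangular(1e4, 0, 1.65, 0.75)) # about (0 + 1.65 + 0.75)/3 = 0.80
rtriangular <- function(n, min, max, mode) {
  if (!(min < max) || mode < min || mode > max) {
    stop("require min < max and mode within [min, max]", call. = FALSE)
  }
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Draw parameter sets for probabilistic analyses
#'
#' One row per simulation: the three per-fortnight incident rates drawn
#' independently from triangular distributions on the configured support with
#' modes at their baseline values, and the two repeat-attendance rates drawn
#' as binomial proportions with the trial arm sizes and observed rates.
#' With `enforce_rate_ordering = TRUE` in the configuration, draws violating
#' `r_hs2 < r_hs2e < r_na` are rejected and redrawn (the default keeps them,
#' treating the rates as fully independent).
#'
#' Uses the current RNG state; call `set.seed()` beforehand (or use the
#' `seed` arguments of [run_psa()] and friends) for reproducibility.
#'
#' @param n Number of draws.
#' @param config Model configuration.
#' @return A tibble with columns `r_hs2`, `r_hs2e`, `r_na`, `rate_hs2`,
#'   `rate_sc`.
#' @export
sample_draws <- function(n, config = default_config()) {
  supp <- config$psa$rate_support
  modes <- config$psa$rate_modes
  # rate_support is either one common (min, max) pair or a list keyed by
  # rate name, e.g. to shrink each distribution around its own mode
  support_of <- function(name) {
    if (is.list(supp)) supp[[name]] else supp
  }
  draw_one <- function(m, name) {
    s <- support_of(name)
    rtriangular(m, s[1], s[2], modes[[name]])
  }
  draw_rates <- function(m) {
    cbind(r_hs2 = draw_one(m, "r_hs2"),
          r_hs2e = draw_one(m, "r_hs2e"),
          r_na = draw_one(m, "r_na"))
  }
  r <- draw_rates(n)
  if (isTRUE(config$psa$enforce_rate_ordering)) {
    bad <- which(!(r[, 1] < r[, 2] & r[, 2] < r[, 3]))
    while (length(bad)) {
      r[bad, ] <- draw_rates(length(bad))
      bad <- bad[!(r[bad, 1] < r[bad, 2] & r[bad, 2] < r[bad, 3])]
    }
  }
  tr <- config$trial
  tibble::tibble(
    r_hs2 = r[, 1], r_hs2e = r[, 2], r_na = r[, 3],
    rate_hs2 = stats::rbinom(n, tr$hs2[["n"]],
                             config$transitions$hs2$observed_repeat_rate) /
      tr$hs2[["n"]],
    rate_sc = stats::rbinom(n, tr$sc[["n"]],
                            config$transitions$sc$observed_repeat_rate) /
      tr$sc[["n"]]
  )
}

# Map a draw table to the per-arm incident-rate matrices. The HS2 arm's
# types (read+action, read only, no action) take (r_hs2, r_hs2e, r_na); the
# standard-care types (action, no action) take (r_hs2, r_na).
draw_rate_matrices <- function(draws) {
  list(
    hs2 = cbind(draws$r_hs2, draws$r_hs2e, draws$r_na),
    sc = cbind(draws$r_hs2, draws$r_na)
  )
}

ce_quadrant <- function(delta_cost, delta_effect) {
  ifelse(delta_cost >= 0,
         ifelse(delta_effect >= 0, "NE", "NW"),
         ifelse(delta_effect >= 0, "SE", "SW"))
}

#' Probabilistic sensitivity analysis on the cost-effectiveness plane
#'
#' Draws the incident rates and trial repeat rates ([sample_draws()]),
#' recalibrates the severity probabilities of both arms within each draw,
#' evaluates the full model per draw and plots each result as a point on the
#' cost-effectiveness plane: incremental cost (GBP per 100 patients) against
#' recurrent cases avoided (per 100 patients). All other parameters are held
#' at baseline. Draws in which calibration is infeasible (severity
#' probability above 1) are excluded and counted.
#'
#' Quadrants: NW (costlier, less effective — the intervention is dominated)
#' and SE (cheaper, more effective — dominant) are the headline summaries.
#'
#' @param config Model configuration.
#' @param n_sims Number of simulations (default from the configuration).
#' @param seed Optional integer seed.
#' @return A list of class `hs2_psa`: `points` (tibble with `draw`,
#'   `delta_cost`, `delta_effect`, `quadrant`), `quadrants` (tibble with
#'   proportions and Monte-Carlo standard errors), `n_excluded`, `baseline`
#'   (the baseline point) and `seed`.
#' @export
run_psa <- function(config = default_config(),
                    n_sims = config$psa$n_sims, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  draws <- sample_draws(n_sims, config)
  rm <- draw_rate_matrices(draws)
  ev_h <- arm_evaluate("hs2", config, rates = rm$hs2,
                       observed_rate = draws$rate_hs2)
  ev_s <- arm_evaluate("sc", config, rates = rm$sc,
                       observed_rate = draws$rate_sc)
  ok <- ev_h$feasible & ev_s$feasible
  delta_cost <- 100 * (ev_h$total - ev_s$total)
  delta_effect <- 100 * (ev_h$p0 - ev_s$p0)
  points <- tibble::tibble(
    draw = seq_len(n_sims)[ok],
    delta_cost = delta_cost[ok],
    delta_effect = delta_effect[ok],
    quadrant = ce_quadrant(delta_cost[ok], delta_effect[ok])
  )
  n_ok <- nrow(points)
  quad <- table(factor(points$quadrant, levels = c("NE", "NW", "SE", "SW")))
  prop <- as.numeric(quad) / n_ok
  base <- run_baseline(config)
  structure(list(
    points = points,
    quadrants = tibble::tibble(
      quadrant = names(quad),
      n = as.integer(quad),
      proportion = prop,
      mc_se = sqrt(prop * (1 - prop) / n_ok)
    ),
    n_sims = n_sims,
    n_excluded = sum(!ok),
    baseline = c(delta_cost = 100 * base$delta_cost,
                 delta_effect = 100 * base$delta_effect),
    seed = seed
  ), class = "hs2_psa")
}

#' @export
print.hs2_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d simulations (%d excluded)\n",
              x$n_sims, x$n_excluded))
  cat(sprintf("  baseline point: cost %+.0f GBP, effect %+.2f cases per 100 patients\n",
              x$baseline[["delta_cost"]], x$baseline[["delta_effect"]]))
  q <- x$quadrants
  cat(sprintf("  dominated (NW): %.2f%%   dominant (SE): %.2f%%\n",
              100 * q$proportion[q$quadrant == "NW"],
              100 * q$proportion[q$quadrant == "SE"]))
  invisible(x)
}
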