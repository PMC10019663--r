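test_that("ICER division, dominance flags and scale invariance", {
  expect_equal(round(icer(9.29, 0.030)$value, 2), 309.67)
  expect_equal(icer(0, 0.1)$value, 0)

  dom <- icer(-1, 0.1)
  expect_lt(dom$value, 0)
  expect_identical(dom$dominance, "dominant")
  expect_identical(icer(5, -0.1)$dominance, "dominated")

  undef <- icer(5, 0)
  expect_false(undef$defined)
  expect_true(is.na(undef$value))

  # common currency rescaling of both arms rescales the ICER linearly,
  # leaving the cost-per-case ranking invariant
  expect_equal(icer(9.29 * 100, 0.030)$value, icer(9.29, 0.030)$value * 100)
})

test_that("relative risk reduction is the relative change in no-recurrence", {
  expect_equal(round(relative_risk_reduction(0.42404, 0.39400), 1), 7.6)
  expect_equal(relative_risk_reduction(0.4, 0.4), 0)
  expect_equal(relative_risk_reduction(0.5, 0.4), 25)
  expect_error(relative_risk_reduction(0.5, 0), "> 0")
})

test_that("two-proportion z-test reproduces the trial's primary-outcome p-value", {
  res <- efficacy_test(32, 707, 92, 1674)
  expect_equal(round(res$p_value, 2), 0.33)
  expect_equal(res$p1, 32 / 707)

  # identical proportions: no evidence against equality
  expect_equal(efficacy_test(10, 100, 10, 100)$p_value, 1)
  # overwhelming difference
  expect_lt(efficacy_test(0, 100, 50, 100)$p_value, 1e-10)
  expect_error(efficacy_test(5, 0, 1, 10), "positive")
  expect_error(efficacy_test(11, 10, 1, 10), "\\[0, n\\]")
})

test_that("z-test agrees with the uncorrected chi-square test and a
           resampling oracle", {
  cases <- list(c(32, 707, 92, 1674), c(10, 50, 15, 60), c(3, 40, 9, 35))
  for (cs in cases) {
    res <- efficacy_test(cs[1], cs[2], cs[3], cs[4])
    pt <- suppressWarnings(
      stats::prop.test(c(cs[1], cs[3]), c(cs[2], cs[4]), correct = FALSE))
    expect_equal(res$p_value, pt$p.value, tolerance = 1e-10)
    expect_equal(res$z^2, unname(pt$statistic), tolerance = 1e-10)
  }

  # small-count check against binomial resampling under the pooled rate
  set.seed(404)
  cs <- c(10, 50, 15, 60)
  obs <- abs(cs[1] / cs[2] - cs[3] / cs[4])
  pooled <- (cs[1] + cs[3]) / (cs[2] + cs[4])
  sim <- abs(stats::rbinom(4e4, cs[2], pooled) / cs[2] -
               stats::rbinom(4e4, cs[4], pooled) / cs[4])
  p_mc <- mean(sim >= obs - 1e-12)
  expect_equal(efficacy_test(cs[1], cs[2], cs[3], cs[4])$p_value, p_mc,
               tolerance = 0.05)
})

test_that("baseline analysis is internally consistent", {
  res <- run_baseline()
  expect_equal(round(100 * res$p0_hs2, 1), 42.4)
  expect_equal(round(100 * res$p0_sc, 1), 39.4)
  expect_equal(round(res$rrr_percent, 1), 7.6)
  expect_equal(round(res$p4, 3), 0.113)
  expect_equal(round(res$q4, 3), 0.121)
  expect_equal(res$delta_cost,
               res$costs$hs2[5] - res$costs$sc[5], tolerance = 1e-12)
  expect_equal(res$icer$value, res$delta_cost / res$delta_effect,
               tolerance = 1e-12)
  # provider rows add up to the totals
  expect_equal(sum(res$costs$hs2[1:4]), res$costs$hs2[5], tolerance = 1e-9)
  expect_equal(sum(res$costs$sc[1:4]), res$costs$sc[5], tolerance = 1e-9)
})

test_that("one-way sensitivities perturb one parameter and order the tornado", {
  sens <- one_way_sensitivity()
  expect_equal(nrow(sens), 3)
  expect_true(all(is.na(sens$error)))
  expect_true(all(diff(sens$range) <= 1e-12))  # sorted widest first
  expect_true(all(sens$baseline >= pmin(sens$low, sens$high) &
                    sens$baseline <= pmax(sens$low, sens$high)))

  ic <- sens[sens$parameter == "intervention_cost", ]
  expect_equal(ic$low, 6.70)
  expect_equal(ic$high, 18.43)

  # a null perturbation leaves the ICER at baseline
  base <- run_baseline()
  null_scen <- list(list(name = "null", parameter = "intervention_cost",
                         low = 9.95, high = 9.95, baseline = 9.95))
  null_sens <- one_way_sensitivity(default_config(), null_scen)
  expect_equal(null_sens$icer_low, base$icer$value, tolerance = 1e-12)
  expect_equal(null_sens$icer_high, base$icer$value, tolerance = 1e-12)
})

test_that("ICER moves monotonically with intervention cost and severe rate", {
  cfg <- default_config()
  icer_at_cost <- function(cost) {
    c2 <- cfg
    c2$state_costs$intervention$cost <- cost
    run_baseline(c2)$icer$value
  }
  # cheaper intervention, lower ICER (effect difference positive, unchanged)
  i_low <- icer_at_cost(6.70)
  i_base <- icer_at_cost(9.95)
  i_high <- icer_at_cost(18.43)
  expect_lt(i_low, i_base)
  expect_lt(i_base, i_high)

  icer_at_severe <- function(rate) {
    c2 <- cfg
    c2$transitions$hs2$observed_repeat_rate <- rate
    run_baseline(c2)$icer$value
  }
  s_low <- icer_at_severe(0.035)
  s_base <- icer_at_severe(0.045)
  s_high <- icer_at_severe(0.055)
  expect_lt(s_low, s_base)
  expect_lt(s_base, s_high)

  # halving the full-success rate lowers the read+action recurrence
  # probability to 1 - exp(-0.375)
  c2 <- cfg
  c2$transitions$hs2$rates["read_action"] <- 0.375
  arm <- build_arm("hs2", c2)
  p_rec <- 1 - sum(arm$probability[arm$patient_type == "read_action" &
                                     arm$outcome == "none"]) /
    c2$transitions$hs2$stage1[["read_action"]]
  expect_equal(p_rec, 1 - exp(-0.375), tolerance = 1e-12)
})

test_that("infeasible scenario values are reported, not fatal", {
  scen <- list(list(name = "bad severe rate", parameter = "hs2_severe_rate",
                    low = 0.0, high = 0.9, baseline = 0.045))
  sens <- one_way_sensitivity(default_config(), scen)
  expect_false(is.na(sens$error[1]))
  expect_true(is.na(sens$icer_low[1]))
})
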