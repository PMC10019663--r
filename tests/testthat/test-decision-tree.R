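test_that("arm enumeration has the expected pathway structure", {
  hs2 <- build_arm("hs2")
  sc <- build_arm("sc")
  expect_equal(nrow(hs2), 30)
  expect_equal(nrow(sc), 20)
  expect_equal(sum(hs2$ems_attend), 18)
  expect_equal(sum(sc$ems_attend), 12)
  expect_equal(sum(hs2$probability), 1, tolerance = 1e-12)
  expect_equal(sum(sc$probability), 1, tolerance = 1e-12)
  # EMS attends severe recurrences and nothing else
  expect_identical(hs2$ems_attend, hs2$outcome == "HypoS")
  expect_identical(sc$ems_attend, sc$outcome == "HypoS")
  expect_true(all(hs2$probability >= 0 & hs2$probability <= 1))
  expect_true(all(hs2[, c("cost_ems", "cost_iuc", "cost_primary",
                          "cost_secondary")] >= 0))
})

test_that("severity calibration reproduces the derived probabilities", {
  expect_equal(round(severity_pathway_sum("hs2"), 4), 0.3993)
  expect_equal(round(calibrate_severity_probability(0.045, "hs2"), 3), 0.113)
  expect_equal(round(calibrate_severity_probability(0.055, "sc"), 3), 0.121)
  expect_identical(calibrate_severity_probability(0, "hs2"), 0)
  expect_error(calibrate_severity_probability(0.9, "hs2"), "infeasible")
})

test_that("calibration round-trips: attendance probability equals the observed rate", {
  for (rate in c(0.01, 0.045, 0.2)) {
    arm <- build_arm("hs2", p4 = calibrate_severity_probability(rate, "hs2"))
    expect_equal(sum(arm$probability[arm$ems_attend]), rate,
                 tolerance = 1e-12)
  }
  set.seed(401)
  for (i in 1:10) {
    cfg <- random_config()
    for (a in c("hs2", "sc")) {
      arm <- build_arm(a, cfg)
      expect_equal(sum(arm$probability[arm$ems_attend]),
                   cfg$transitions[[a]]$observed_repeat_rate,
                   tolerance = 1e-12)
      expect_equal(sum(arm$probability), 1, tolerance = 1e-9)
    }
  }
})

test_that("baseline outcome distributions match the model's derived values", {
  d_h <- outcome_distribution(build_arm("hs2"))
  d_s <- outcome_distribution(build_arm("sc"))
  expect_equal(round(unname(d_h), 3), c(0.424, 0.531, 0.045))
  expect_equal(round(unname(d_s), 3), c(0.394, 0.551, 0.055))

  # no incidence anywhere: everyone stays recurrence-free
  cfg <- default_config()
  for (a in c("hs2", "sc")) {
    cfg$transitions[[a]]$rates[] <- 0
    cfg$transitions[[a]]$observed_repeat_rate <- 0
  }
  expect_equal(unname(outcome_distribution(build_arm("hs2", cfg))),
               c(1, 0, 0))
})

test_that("pathway enumeration and recursive evaluator agree", {
  set.seed(402)
  for (i in 1:15) {
    cfg <- random_config()
    for (a in c("hs2", "sc")) {
      enum <- build_arm(a, cfg)
      costs <- expected_costs(enum)
      rec <- evaluate_arm_recursive(a, cfg)
      expect_equal(costs$cost[costs$provider == "total"], rec$total,
                   tolerance = 1e-9)
      expect_equal(unname(costs$cost[1:4]), unname(rec$cost),
                   tolerance = 1e-9)
      d <- outcome_distribution(enum)
      expect_equal(unname(rec$outcomes[c("none", "HypoNS", "HypoS")]),
                   unname(d), tolerance = 1e-9)
    }
  }
})

test_that("vectorised evaluator agrees with the pathway enumeration", {
  set.seed(403)
  for (i in 1:10) {
    cfg <- random_config()
    for (a in c("hs2", "sc")) {
      ev <- hs2cea:::arm_evaluate(a, cfg)
      enum <- build_arm(a, cfg)
      costs <- expected_costs(enum)
      expect_equal(ev$total, costs$cost[costs$provider == "total"],
                   tolerance = 1e-9)
      expect_equal(unname(ev$cost[1, ]), unname(costs$cost[1:4]),
                   tolerance = 1e-9)
      expect_equal(ev$p0, unname(outcome_distribution(enum)["p0"]),
                   tolerance = 1e-12)
      tc <- patient_type_costs(enum)
      expect_equal(unname(ev$type_total[1, ]), tc$cost, tolerance = 1e-9)
    }
  }
})

test_that("a hand-enumerated single-type arm matches the evaluators", {
  # one standard-care patient type, round numbers, all ten pathway products
  # written out explicitly
  cfg <- default_config()
  cfg$transitions$sc$stage1 <- c(action = 1, no_action = 0)
  cfg$transitions$sc$rates <- c(action = log(2), no_action = 1)  # p2 = 1/2
  cfg$transitions$sc$observed_repeat_rate <- 0.15
  p2 <- 0.5; p31 <- 0.4; p32 <- 0.35
  p4 <- 0.15 / (p2 * (p31 + p32))
  p5 <- 0.6; p6 <- 1 / 3
  sm <- 33.53912500  # 0.10625*(170.66+109.92) + 0.03125*(73.57+45.71)
  by_hand <-
    39 +                                                   # GP consult
    p2 * p31 * p4 * p5 * p6 * (7.33 + 257.34 + 1478.13) +
    p2 * p31 * p4 * p5 * (1 - p6) * (7.33 + 257.34 + 168.89) +
    p2 * p31 * p4 * (1 - p5) * (7.33 + 209.38) +
    p2 * p31 * (1 - p4) * (7.33 + 47.49) +
    p2 * p32 * p4 * p5 * p6 * (7.33 + 7.33 + 257.34 + 1478.13) +
    p2 * p32 * p4 * p5 * (1 - p6) * (7.33 + 7.33 + 257.34 + 168.89) +
    p2 * p32 * p4 * (1 - p5) * (7.33 + 7.33 + 209.38) +
    p2 * p32 * (1 - p4) * (7.33 + 71.94) +
    p2 * (1 - p31 - p32) * sm
  enum <- expected_costs(build_arm("sc", cfg))
  expect_equal(enum$cost[enum$provider == "total"], by_hand,
               tolerance = 1e-9)
  expect_equal(evaluate_arm_recursive("sc", cfg)$total, by_hand,
               tolerance = 1e-9)
})

test_that("expected costs respect the accounting identity and monotonicity", {
  arm <- build_arm("hs2")
  costs <- expected_costs(arm)
  expect_equal(costs$cost[5], sum(costs$cost[1:4]), tolerance = 1e-12)

  # raising a unit cost cannot lower the expected total
  cfg_up <- default_config()
  cfg_up$state_costs$str$cost <- cfg_up$state_costs$str$cost + 100
  up <- expected_costs(build_arm("hs2", cfg_up))
  expect_gt(up$cost[5], costs$cost[5])

  # raising an incident rate strictly lowers the no-recurrence probability
  cfg_r <- default_config()
  cfg_r$transitions$hs2$rates["read_only"] <- 1.2
  expect_lt(outcome_distribution(build_arm("hs2", cfg_r))["p0"],
            outcome_distribution(arm)["p0"])
})

test_that("patient-type costs decompose the arm expectation", {
  for (a in c("hs2", "sc")) {
    arm <- build_arm(a)
    tc <- patient_type_costs(arm)
    total <- expected_costs(arm)$cost[5]
    expect_equal(sum(tc$stage1_prob * tc$cost), total, tolerance = 1e-9)
  }
  # a type with no incidence and no stage-1 action costs nothing
  cfg <- default_config()
  cfg$transitions$sc$rates["no_action"] <- 0
  tc <- patient_type_costs(build_arm("sc", cfg))
  expect_equal(tc$cost[tc$patient_type == "no_action"], 0)
})

test_that("the pathway audit table is written for both arms", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- write_pathways(default_config(), path)
  expect_true(file.exists(path))
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 50)
  expect_equal(sum(back$probability), 2, tolerance = 1e-9)
  expect_setequal(unique(back$arm), c("hs2", "sc"))
})
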