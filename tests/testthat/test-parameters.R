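test_that("rate-to-probability transform matches its closed form and bounds", {
  expect_equal(round(rate_to_probability(0.75), 2), 0.53)
  expect_equal(round(rate_to_probability(0.9), 2), 0.59)
  expect_equal(rate_to_probability(0.9), 1 - exp(-0.9), tolerance = 1e-12)
  expect_identical(rate_to_probability(0), 0)

  r <- seq(0, 1.65, by = 0.01)
  p <- rate_to_probability(r)
  expect_true(all(diff(p) > 0))          # strictly increasing
  expect_true(all(p >= 0 & p < 1))
  expect_equal(probability_to_rate(p), r, tolerance = 1e-10)  # inverse

  expect_error(rate_to_probability(-0.1), "rate")
  expect_error(probability_to_rate(1), "probability")
})

test_that("annual incidence per 1,000 person-years scales to fortnight rates", {
  expect_equal(round(annual_rate_to_fortnight(42890), 2), 1.65)
  expect_equal(signif(annual_rate_to_fortnight(0.072), 2), 2.8e-6)
  expect_identical(annual_rate_to_fortnight(0), 0)
  expect_error(annual_rate_to_fortnight(-1), "rate")
})

test_that("intervention cost arithmetic reproduces the out-/in-hours costs", {
  expect_equal(intervention_cost(2, 2.55, 1.60), 6.70)
  expect_equal(intervention_cost(6.6, 2.55, 1.60), 18.43)
  expect_equal(intervention_cost(0, 2.55, 1.60), 1.60)
  expect_error(intervention_cost(-1), ">= 0")
})

test_that("weighted administration time averages the stratum medians", {
  expect_equal(round(weighted_admin_time(0.28, 6.6, 2), 1), 3.3)
  expect_equal(weighted_admin_time(1, 6.6, 2), 6.6)
  expect_equal(weighted_admin_time(0.5, 4, 4), 4)
  expect_error(weighted_admin_time(1.2, 1, 1), "day_share")
})

test_that("self-manage expected costs follow from the mixes and the schedule", {
  cfg <- default_config()
  expect_equal(round(self_manage_cost(cfg$self_manage$other, cfg), 2), 33.54)
  expect_equal(round(self_manage_cost(cfg$self_manage$read_action, cfg), 2),
               25.03)
  expect_equal(self_manage_cost(c(0, 0, 0, 0, 1), cfg), 0)
  expect_error(self_manage_cost(c(0.5, 0.5, 0.5, 0, 0), cfg), "sum to 1")
  expect_error(self_manage_cost(c(1, 0, 0, 0), cfg), "5 proportions")
})

test_that("eligible population applies the exclusion fractions", {
  res <- eligible_population(7.9e6, 0.006, 0.05, 0.6)
  expect_equal(res$exact, 18012, tolerance = 1e-9)
  expect_equal(res$rounded, 18000)
  expect_equal(eligible_population(7.9e6, 0, 0.05, 0.6)$exact, 0)
  expect_equal(eligible_population(1e6, 0.01, 0, 0)$exact, 10000)
})

test_that("averaged decrements are the day-share-weighted means", {
  ad <- averaged_decrements(default_config())
  expect_equal(ad[["ns"]], 0.28 * 0.004 + 0.72 * 0.007, tolerance = 1e-12)
  expect_equal(ad[["s"]], 0.28 * 0.062 + 0.72 * 0.057, tolerance = 1e-12)
  expect_equal(round(ad[["ns"]], 3), 0.006)
  expect_equal(round(ad[["s"]], 3), 0.058)

  cfg <- default_config()
  cfg$utilities$use_alt_decrements <- TRUE
  expect_equal(unname(averaged_decrements(cfg)), c(0.014, 0.047))
})

test_that("unit-cost lookup rejects unknown codes", {
  cfg <- default_config()
  expect_equal(unit_cost(cfg, "STR"), 209.38)
  expect_error(unit_cost(cfg, "ZZZ"), "unknown")
})

test_that("configuration validation rejects broken parameter sets", {
  cfg <- default_config()
  expect_silent(validate_config(cfg))

  bad <- cfg
  bad$transitions$hs2$p31["read_only"] <- 1.2
  expect_error(validate_config(bad), "p31")

  bad <- cfg
  bad$transitions$sc$p31["action"] <- 0.7
  bad$transitions$sc$p32["action"] <- 0.5
  expect_error(validate_config(bad), "p31 \\+ p32")

  bad <- cfg
  bad$self_manage$other <- c(0.2, 0.2, 0.2, 0.2, 0.1)
  expect_error(validate_config(bad), "sum to 1")

  bad <- cfg
  bad$cost_schedule$items$STR <- NULL
  expect_error(validate_config(bad), "missing codes")

  bad <- cfg
  bad$cost_schedule$items$GP$cost <- -1
  expect_error(validate_config(bad), ">= 0")
})

test_that("configurations round-trip through YAML", {
  cfg <- default_config()
  cfg$transitions$hs2$observed_repeat_rate <- 0.0415
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- load_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-9)
  expect_identical(back$transitions$hs2$observed_repeat_rate, 0.0415)
  expect_identical(names(back$transitions$hs2$stage1),
                   names(cfg$transitions$hs2$stage1))
})

test_that("the shipped baseline YAML matches the in-code defaults", {
  path <- system.file("extdata", "hs2_baseline.yaml", package = "hs2cea")
  expect_true(nzchar(path))
  expect_equal(unclass(load_config(path)), unclass(default_config()),
               tolerance = 1e-9)
})
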