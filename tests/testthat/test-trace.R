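test_that("identity chain keeps the cohort pinned in post-DFU", {
  tr <- run_cohort_trace(transition_parameters(),
                         model_config(max_age_years = 70))
  expect_equal(unname(tr$occupancy[, "post_dfu"]), rep(1, tr$n_cycles + 1))
})

test_that("immediate death absorbs the whole cohort after one cycle", {
  p <- transition_parameters(c("post_dfu.to.death" = 1))
  tr <- run_cohort_trace(p, model_config())
  expect_equal(unname(tr$occupancy[2, "death"]), 1)
  # early stop: residual alive fraction below tolerance after cycle 1
  expect_equal(tr$n_cycles, 1)
})

test_that("two-state geometric survival matches the closed form", {
  q <- 0.03
  p <- transition_parameters(c("post_dfu.to.death" = q))
  tr <- run_cohort_trace(p, model_config(max_age_years = 77,
                                         residual_alive_tolerance = 0))
  cycles <- 0:tr$n_cycles
  expect_lt(max(abs(tr$occupancy[, "post_dfu"] - (1 - q)^cycles)), 1e-12)
})

test_that("trace refuses unvalidated parameters and empty horizons", {
  p <- placeholder_transitions()
  p$validated <- FALSE
  expect_error(run_cohort_trace(p, model_config()), "validated")
  expect_error(model_config(baseline_age_years = 67, max_age_years = 67),
               "exceed")
})

test_that("discount factors follow the per-cycle convention", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(24, 0), 1)
  expect_equal(discount_factor(12, 0.035), 1 / 1.035)
  expect_equal(discount_factor(12, 0.035), 0.966184, tolerance = 1e-6)
  # annual step: constant within a year, 1/(1+r) after 12 cycles
  expect_equal(discount_factor(11, 0.035, "annual_step"), 1)
  expect_equal(discount_factor(12, 0.035, "annual_step"), 1 / 1.035)
  expect_error(discount_factor(-1, 0.035), "non-negative")
})

test_that("outcome accumulation matches hand sums for a pinned cohort", {
  # immortal cohort in post-DFU for 12 cycles, no discounting
  p <- transition_parameters()
  cfg <- model_config(baseline_age_years = 67, max_age_years = 68,
                      half_cycle_correction = FALSE)
  tr <- run_cohort_trace(p, cfg)
  expect_equal(tr$n_cycles, 12)
  econ <- economic_parameters(discount_outcomes = 0, discount_costs = 0)
  out <- accumulate_outcomes(tr, econ, include_app_cost = FALSE)
  expect_equal(out$discounted_qalys, 0.64)            # 12 * 0.64/12
  expect_equal(out$discounted_costs, 2168.40)         # 12 * 180.70
  with_app <- accumulate_outcomes(tr, econ, include_app_cost = TRUE)
  expect_equal(with_app$discounted_costs, 2168.40 + 12 * 4.99)  # 2228.28
  # zero utilities and costs give zero totals
  z <- economic_parameters(utilities = setNames(rep(0, 6), dfu_states()),
                           monthly_costs = setNames(rep(0, 6), dfu_states()),
                           app_price_monthly = 0,
                           discount_outcomes = 0, discount_costs = 0)
  expect_equal(accumulate_outcomes(tr, z),
               list(discounted_qalys = 0, discounted_costs = 0))
})

test_that("half-cycle correction averages adjacent occupancy rows", {
  p <- transition_parameters(c("post_dfu.to.death" = 0.5))
  econ <- economic_parameters(discount_outcomes = 0, discount_costs = 0)
  cfg_off <- model_config(max_age_years = 68, half_cycle_correction = FALSE,
                          residual_alive_tolerance = 0)
  cfg_on <- model_config(max_age_years = 68, half_cycle_correction = TRUE,
                         residual_alive_tolerance = 0)
  tr <- run_cohort_trace(p, cfg_off)
  tr_on <- run_cohort_trace(p, cfg_on)
  off <- accumulate_outcomes(tr, econ)$discounted_qalys
  on <- accumulate_outcomes(tr_on, econ)$discounted_qalys
  # survival halves each cycle: end-of-cycle sum vs trapezoid sum
  n <- tr$n_cycles
  s_end <- sum(0.5^(1:n)) * 0.64 / 12
  s_avg <- sum((0.5^(0:(n - 1)) + 0.5^(1:n)) / 2) * 0.64 / 12
  expect_equal(off, s_end)
  expect_equal(on, s_avg)
})

test_that("mass is conserved and death is monotone over random draws", {
  for (seed in 1:25) {
    p <- random_params(seed)
    tr <- run_cohort_trace(p, model_config())
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
    expect_true(all(tr$occupancy >= 0 & tr$occupancy <= 1 + 1e-12))
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-12))
  }
})

test_that("discounted QALYs never increase when mortality increases", {
  econ <- economic_parameters()
  cfg <- model_config()
  for (seed in 1:5) {
    p <- random_params(seed)
    base_q <- accumulate_outcomes(run_cohort_trace(p, cfg), econ)$discounted_qalys
    for (key in c("transitions.post_dfu.to.death",
                  "transitions.severe_dfu.to.death",
                  "transitions.post_amputation.to.death")) {
      m <- dfuheor:::set_model_parameter(
        key, min(1, dfuheor:::get_model_parameter(key, p, econ) + 0.05),
        p, econ)
      q2 <- accumulate_outcomes(run_cohort_trace(m$params, cfg),
                                m$econ)$discounted_qalys
      expect_lte(q2, base_q + 1e-12)
    }
  }
})

test_that("trace converts to a tidy per-cycle data frame", {
  tr <- run_cohort_trace(placeholder_transitions(), model_config())
  df <- as.data.frame(tr)
  expect_equal(names(df), c("cycle", "age_years", dfu_states(),
                            "discount_out", "discount_cost"))
  expect_equal(nrow(df), tr$n_cycles + 1)
  expect_equal(df$age_years[1], 67)
})
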