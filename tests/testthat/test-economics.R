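sr <- function(q, c, label = "x") strategy_result(label, q, c)

test_that("ICER classifies the cost-effectiveness plane quadrants", {
  r <- icer(sr(11, 30000), sr(10, 10000))
  expect_equal(r$icer, 20000)
  expect_equal(r$category, "ICER")
  expect_false(r$southwest)

  expect_equal(icer(sr(10.01, 9990), sr(10, 10000))$category, "DOMINANT")
  expect_equal(icer(sr(9.9, 10100), sr(10, 10000))$category, "DOMINATED")
  expect_equal(icer(sr(10, 10500), sr(10, 10000))$category, "ZERO_EFFECT")
  sw <- icer(sr(9.9, 8000), sr(10, 10000))
  expect_equal(sw$category, "ICER")
  expect_true(sw$southwest)
})

test_that("net monetary benefit is wtp * dQ - dC", {
  expect_equal(nmb(sr(11, 30000), sr(10, 10000), 20000), 0)
  expect_equal(nmb(sr(10, 10050), sr(10, 10000), 20000), -50)
  expect_equal(nmb(sr(10.05, 10400), sr(10, 10000), 20000), 600)
  expect_error(nmb(sr(1, 1), sr(1, 1), -5), "non-negative")
})

test_that("NMB is affine in wtp and zero at the ICER point", {
  a <- sr(10.3, 14000); b <- sr(10, 10000)
  ic <- icer(a, b)
  expect_lt(abs(nmb(a, b, ic$icer)), 1e-9)
  w <- c(0, 10000, 30000)
  vals <- vapply(w, function(x) nmb(a, b, x), numeric(1))
  expect_equal(diff(vals) / diff(w), rep(ic$delta_qaly, 2))
})

test_that("strategy arms are identical when the app is free and inert", {
  p <- placeholder_transitions()
  cfg <- model_config()
  e0 <- economic_parameters(app_price_monthly = 0)
  s <- evaluate_strategies(p, e0, cfg, rr = 1)
  expect_equal(s$intervention$discounted_qalys, s$comparator$discounted_qalys)
  expect_equal(s$intervention$discounted_costs, s$comparator$discounted_costs)

  # priced but inert: pure cost difference
  e <- economic_parameters()
  s2 <- evaluate_strategies(p, e, cfg, rr = 1)
  expect_equal(s2$intervention$discounted_qalys, s2$comparator$discounted_qalys)
  expect_gt(s2$intervention$discounted_costs, s2$comparator$discounted_costs)
})

test_that("halving recurrence gains QALYs", {
  p <- placeholder_transitions()
  s <- evaluate_strategies(p, economic_parameters(), model_config(), rr = 0.5)
  expect_gt(s$intervention$discounted_qalys, s$comparator$discounted_qalys)
})

test_that("threshold solver agrees with the grid oracle on the placeholder set", {
  p <- placeholder_transitions()
  econ <- economic_parameters()
  cfg <- model_config()
  th <- threshold_rr(p, econ, cfg, 20000)
  expect_equal(th$status, "ok")
  expect_equal(th$icer, 20000, tolerance = 1e-4)
  oracle <- threshold_grid_oracle(p, econ, cfg, 20000)
  expect_lt(abs(th$rr - oracle), 0.001 + 1e-9)
})

test_that("threshold round-trips: re-evaluating at rr* reproduces the target ICER", {
  p <- placeholder_transitions()
  econ <- economic_parameters(compliance = 1)
  cfg <- model_config()
  th <- threshold_rr(p, econ, cfg, 20000)
  s <- evaluate_strategies(p, econ, cfg, th$rr)
  ic <- icer(s$intervention, s$comparator)
  expect_lt(abs(ic$icer - 20000) / 20000, 1e-5)
})

test_that("free effective app dominates; zero compliance has no threshold", {
  p <- placeholder_transitions()
  cfg <- model_config()
  th_free <- threshold_rr(p, economic_parameters(app_price_monthly = 0),
                          cfg, 20000)
  expect_equal(th_free$status, "dominant_at_rr1")
  expect_equal(th_free$rr, 1)

  th_nc <- threshold_rr(p, economic_parameters(compliance = 0), cfg, 20000)
  expect_equal(th_nc$status, "no_threshold")
  expect_true(is.na(th_nc$rr))
  expect_error(threshold_rr(p, economic_parameters(), cfg, -1), "positive")
})

test_that("scenario runner orders thresholds by price and is deterministic", {
  p <- placeholder_transitions()
  econ <- economic_parameters()
  cfg <- model_config()
  rep1 <- run_scenarios(p, econ, cfg)
  rep2 <- run_scenarios(p, econ, cfg)
  expect_identical(rep1, rep2)
  expect_equal(rep1$scenario, c("free", "monthly", "annual"))
  # cheaper app needs less effect: threshold rr is non-decreasing as price falls
  rr_monthly <- rep1$threshold_rr[rep1$scenario == "monthly"]
  rr_annual <- rep1$threshold_rr[rep1$scenario == "annual"]
  expect_gte(rr_annual, rr_monthly)
  expect_error(run_scenarios(p, econ, cfg, pricing = "weekly"),
               "valid options")
})
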