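make_test_inputs <- function(n = 250, seed = 31) {
  list(cohort = generate_cohort(default_imss_spec(n = n, seed = seed)),
       params = disease_params())
}

test_that("the base-case scenario is the plain pipeline run", {
  inp <- make_test_inputs()
  res <- run_scenario(scenario_spec("base_case", seed = 7), inp$cohort,
                      inp$params, horizon = 40)
  fx <- treatment_effects(baseline_hba1c = mean(inp$cohort$hba1c),
                          mdi_rate = mean(inp$cohort$severe_hypo_rate),
                          mean_age = mean(inp$cohort$age))
  a <- aggregate_arm(simulate_arm(inp$cohort, inp$params, fx, "CSII", 40, seed = 7))
  b <- aggregate_arm(simulate_arm(inp$cohort, inp$params, fx, "MDI", 40, seed = 7))
  direct <- cea_compare(a, b)
  expect_equal(res$delta_cost, direct$delta_cost)
  expect_equal(res$delta_qaly, direct$delta_qaly)
  expect_equal(res$icer_per_qaly$value, direct$icer_per_qaly$value)
})

test_that("scenario runs are reproducible given a seed", {
  inp <- make_test_inputs(150)
  s <- scenario_spec("base_case", seed = 3)
  r1 <- run_scenario(s, inp$cohort, inp$params, horizon = 30)
  r2 <- run_scenario(s, inp$cohort, inp$params, horizon = 30)
  expect_identical(glance(r1), glance(r2))
})

test_that("halving the HbA1c benefit shrinks the QALY gain and raises the ICER", {
  inp <- make_test_inputs(400)
  base <- run_scenario(scenario_spec("base", seed = 5), inp$cohort,
                       inp$params, horizon = 50)
  half <- run_scenario(scenario_spec("half", hba1c_effect_override = -0.6,
                                     seed = 5),
                       inp$cohort, inp$params, horizon = 50)
  expect_lt(half$delta_qaly, base$delta_qaly)
  expect_gt(half$icer_per_qaly$value, base$icer_per_qaly$value)
})

test_that("discount overrides move totals in the expected direction", {
  inp <- make_test_inputs(150)
  base <- run_scenario(scenario_spec("base", seed = 5), inp$cohort,
                       inp$params, horizon = 40)
  high <- run_scenario(scenario_spec("disc7",
                                     discount_override = discount_spec(0.07, 0.07),
                                     seed = 5),
                       inp$cohort, inp$params, horizon = 40)
  expect_lt(high$csii$total_cost, base$csii$total_cost)
  expect_lt(high$csii$qalys, base$csii$qalys)
})

test_that("subgroup filters partition the cohort and error when empty", {
  inp <- make_test_inputs(300)
  lo <- run_scenario(scenario_spec("lo", subgroup = "hba1c_le_9", seed = 2),
                     inp$cohort, inp$params, horizon = 30)
  hi <- run_scenario(scenario_spec("hi", subgroup = "hba1c_gt_9", seed = 2),
                     inp$cohort, inp$params, horizon = 30)
  expect_equal(lo$csii$n + hi$csii$n, nrow(inp$cohort))
  # the poorly controlled subgroup gets a larger regression effect, so a
  # larger QALY gain per patient is expected under coupling
  expect_gt(hi$delta_qaly, lo$delta_qaly)
  controlled <- inp$cohort[inp$cohort$hba1c <= 9, , drop = FALSE]
  expect_error(run_scenario(scenario_spec("none", subgroup = "hba1c_gt_9"),
                            controlled, inp$params, horizon = 10),
               "no patients")
  expect_error(scenario_spec("bad", subgroup = "hba1c_gt_12"), "unknown")
})

test_that("indirect costs only enter the secondary scenario", {
  inp <- make_test_inputs(120)
  dur <- disability_durations(myocardial_infarction = 60, stroke = 90,
                              severe_hypo = 3)
  base <- run_scenario(scenario_spec("base", seed = 4), inp$cohort,
                       inp$params, horizon = 30, durations = dur)
  sec <- run_scenario(scenario_spec("sec", include_indirect_costs = TRUE,
                                    seed = 4),
                      inp$cohort, inp$params, horizon = 30, durations = dur)
  expect_equal(base$csii$indirect_cost, 0)
  expect_gt(sec$csii$indirect_cost, 0)
  expect_gt(sec$csii$total_cost, base$csii$total_cost)
  # QALYs are unaffected by costing
  expect_equal(sec$csii$qalys, base$csii$qalys)
})

test_that("the suite report has one row per scenario with unique names", {
  inp <- make_test_inputs(150)
  specs <- list(scenario_spec("a", seed = 1), scenario_spec("a", seed = 1),
                scenario_spec("b", hba1c_effect_override = -0.6, seed = 1))
  rep <- run_suite(specs, inp$cohort, inp$params, horizon = 20)
  expect_equal(nrow(rep), 3)
  expect_equal(anyDuplicated(rep$scenario), 0)
  expect_true(all(c("icer_per_qaly", "icer_per_qaly_usd", "cost_csii_usd") %in%
                    names(rep)))
  # USD columns derive from MXN at the fixed rate
  expect_equal(rep$cost_csii_usd, to_usd(rep$cost_csii))
  expect_error(run_suite(list(), inp$cohort), "at least one")
  # default suite covers the nine published sensitivity rows
  expect_length(default_scenario_suite(), 9)
})
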