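test_that("hazard adjustment is log-linear in HbA1c", {
  expect_equal(adjust_hazard(0.02, 1.1, 9.2, 9.2), 0.02)   # identity at ref
  expect_equal(adjust_hazard(0.02, 1.0, 14, 9.2), 0.02)    # rr = 1 flat
  expect_equal(adjust_hazard(0.02, 1.1, 11.2, 9.2), 0.02 * 1.21)
  expect_equal(hazard_to_prob(0), 0)
  expect_lt(hazard_to_prob(100), 1 + 1e-12)
  expect_error(adjust_hazard(-0.1, 1.1, 9, 9), ">= 0")
})

test_that("stepping a patient honours contracts and degenerate configs", {
  co <- generate_cohort(point_spec(1, seed = 1))
  st <- new_patient_state(co[1, ], null_effects(), "MDI")
  # all hazards zero, mortality zero: only age advances
  p0 <- toy_params(q = 0)
  st1 <- withr::with_seed(1, step_patient(st, p0, cycle = 1))
  expect_true(st1$alive)
  expect_equal(st1$age, st$age + 1)
  expect_length(st1$events_this_cycle$incident, 0)
  # dead patients cannot be stepped
  st1$alive <- FALSE
  expect_error(step_patient(st1, p0), "dead")
  # certain hazard with certain fatality kills in the same cycle
  pfatal <- toy_params(q = 0, complications = one_complication(hazard = 1e9, fatality = 1))
  st2 <- withr::with_seed(2, step_patient(st, pfatal, cycle = 1))
  expect_false(st2$alive)
  expect_equal(st2$events_this_cycle$incident, "neuropathy")
})

test_that("acute severe-hypoglycemia counts have the Poisson mean of the rate", {
  co <- generate_cohort(point_spec(20000, seed = 5))
  sim <- simulate_arm(co, toy_params(q = 0), null_effects(22.4), "MDI",
                      horizon_years = 5, seed = 9)
  counts <- as.vector(sim$acute$severe_hypo) # 1e5 patient-cycles
  m <- mean(counts)
  expect_lt(abs(m - 0.224), 3 * sqrt(0.224 / length(counts)))
})

test_that("simulation horizon and certain-death configs behave exactly", {
  co <- generate_cohort(point_spec(20, seed = 2))
  s1 <- simulate_arm(co, toy_params(q = 0), null_effects(), "MDI",
                     horizon_years = 1, seed = 1)
  expect_true(all(life_years(s1) == 1))
  s2 <- simulate_arm(co, toy_params(q = 1), null_effects(), "MDI",
                     horizon_years = 10, seed = 1)
  expect_true(all(s2$death_cycle == 1))
  expect_true(all(life_years(s2) == 1))
})

test_that("null effects with common random numbers make the arms identical", {
  co <- generate_cohort(default_imss_spec(n = 300, seed = 3))
  fx <- null_effects()
  p <- disease_params()
  a <- simulate_arm(co, p, fx, "CSII", 70, seed = 11)
  b <- simulate_arm(co, p, fx, "MDI", 70, seed = 11)
  expect_identical(a$onset, b$onset)
  expect_identical(a$death_cycle, b$death_cycle)
  expect_identical(a$acute, b$acute)
})

test_that("lower HbA1c and hypoglycemia rates never hurt under coupling", {
  co <- generate_cohort(default_imss_spec(n = 2000, seed = 4))
  fx <- treatment_effects()
  p <- disease_params()
  csii <- simulate_arm(co, p, fx, "CSII", 70, seed = 21)
  mdi <- simulate_arm(co, p, fx, "MDI", 70, seed = 21)
  # life-years are per-patient monotone (fatal onsets can only be delayed)
  expect_true(all(life_years(csii) >= life_years(mdi)))
  expect_gt(mean(life_years(csii)), mean(life_years(mdi)) - 1e-12)
  # per-patient complication counts are monotone under a fatality-free
  # configuration (equal survival removes censoring differences)
  p0 <- p
  p0$complications$fatality_prob[] <- 0
  csii0 <- simulate_arm(co, p0, fx, "CSII", 70, seed = 22)
  mdi0 <- simulate_arm(co, p0, fx, "MDI", 70, seed = 22)
  expect_identical(csii0$death_cycle, mdi0$death_cycle)
  expect_true(all(complication_counts(csii0) <= complication_counts(mdi0)))
  expect_true(all(csii0$acute$severe_hypo <= mdi0$acute$severe_hypo))
})

test_that("halving all hazards never decreases any patient's life-years", {
  co <- generate_cohort(default_imss_spec(n = 1500, seed = 6))
  fx <- null_effects()
  p_full <- disease_params()
  p_half <- p_full
  p_half$complications$baseline_hazard <- p_half$complications$baseline_hazard / 2
  full <- simulate_arm(co, p_full, fx, "MDI", 70, seed = 31)
  half <- simulate_arm(co, p_half, fx, "MDI", 70, seed = 31)
  expect_true(all(life_years(half) >= life_years(full)))
  expect_true(all(complication_counts(half) <= complication_counts(full) |
                    life_years(half) > life_years(full)))
})

test_that("predecessor prerequisites gate onsets", {
  co <- generate_cohort(default_imss_spec(n = 500, seed = 8))
  sim <- simulate_arm(co, disease_params(), null_effects(), "MDI", 70, seed = 41)
  on <- sim$onset
  pred_ok <- function(succ, pred) {
    s <- on[, succ]; p <- on[, pred]
    # gating applies to simulated onsets; baseline-prevalent successors
    # (onset 0) come from the independent published prevalences
    sim_on <- !is.na(s) & s >= 1
    all(!sim_on | (!is.na(p) & p <= s))
  }
  expect_true(pred_ok("proliferative_retinopathy", "background_retinopathy"))
  expect_true(pred_ok("gross_proteinuria", "microalbuminuria"))
  expect_true(pred_ok("end_stage_renal_disease", "gross_proteinuria"))
  expect_true(pred_ok("uninfected_ulcer", "neuropathy"))
  expect_true(pred_ok("amputation", "uninfected_ulcer"))
  # dead patients accrue nothing after their death cycle
  dead <- !is.na(sim$death_cycle)
  expect_true(all(on[dead, , drop = FALSE] <= sim$death_cycle[dead],
                  na.rm = TRUE))
})

test_that("time free of a complication follows the censoring convention", {
  co <- generate_cohort(point_spec(5000, seed = 9))
  # geometric onset with p = 0.5, no death: mean onset cycle ~ 1/p = 2
  h <- -log(1 - 0.5)
  sim <- simulate_arm(co, toy_params(q = 0, complications = one_complication(hazard = h)),
                      null_effects(), "MDI", 60, seed = 51)
  tf <- time_free_of(sim, "neuropathy")
  se <- sqrt(2 / 5000) # geometric variance (1-p)/p^2 = 2 at p = 0.5
  expect_lt(abs(tf - 2), 4 * se)
  # onset certain in cycle 1
  sim1 <- simulate_arm(co, toy_params(q = 0, complications = one_complication(hazard = 1e9)),
                       null_effects(), "MDI", 10, seed = 52)
  expect_equal(time_free_of(sim1, "neuropathy"), 1)
  # no onsets anywhere: mean equals mean observed lifetime
  sim0 <- simulate_arm(co, toy_params(q = 0.3, complications = one_complication(hazard = 0)),
                       null_effects(), "MDI", 50, seed = 53)
  expect_equal(time_free_of(sim0, "neuropathy"), mean(life_years(sim0)))
  expect_error(time_free_of(sim0, "no_such_state"), "unknown")
})

test_that("trajectories export one record per lived cycle", {
  co <- generate_cohort(default_imss_spec(n = 20, seed = 10))
  sim <- simulate_arm(co, disease_params(), null_effects(), "MDI", 5, seed = 61)
  tr <- as_trajectories(sim)
  expect_equal(nrow(tr), sum(life_years(sim)))
  expect_true(all(tr$cycle >= 1 & tr$cycle <= 5))
})

test_that("disease parameters round-trip through YAML", {
  p <- disease_params()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_disease_params(p, f)
  p2 <- read_disease_params(f)
  expect_equal(as.data.frame(p2$complications), as.data.frame(p$complications))
  expect_equal(p2$acute_rates, p$acute_rates)
  expect_equal(p2$reference_hba1c, p$reference_hba1c)
  # invalid configs are rejected
  expect_error(disease_params(mortality = constant_mortality(1.5)), "\\[0, 1\\]")
  bad <- default_complications()
  bad$rr_per_pct[1] <- 0
  expect_error(disease_params(complications = bad), "> 0")
})
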