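test_that("the subsequent-year rule reproduces all five published rows to the centavo", {
  # event-year cost -> each-subsequent-year cost
  expect_equal(subsequent_year_cost(267057.59), 29673.07)  # MI
  expect_equal(subsequent_year_cost(108136.66), 12015.18)  # angina
  expect_equal(subsequent_year_cost(155593.67), 17288.19)  # CHF
  expect_equal(subsequent_year_cost(41540.56), 4615.62)    # stroke
  expect_equal(subsequent_year_cost(83605.69), 9289.52)    # PVD
  expect_equal(subsequent_year_cost(0), 0)
  expect_error(subsequent_year_cost(-1), ">= 0")
})

test_that("currency conversion matches the published dollar figures", {
  expect_equal(to_usd(53568), 2912.89)
  expect_equal(to_usd(22884.97), 1244.42)
  expect_equal(to_usd(0), 0)
  # round trip within rounding
  x <- c(123.45, 98765.43)
  expect_equal(to_usd(x) * 18.390, x, tolerance = 0.01 * 18.390)
})

test_that("DRG inflation applies the single published rate", {
  expect_equal(inflate_drg(100), 108.65)
  expect_equal(inflate_drg(0), 0)
  expect_equal(inflate_drg(123.45) / (1 + 0.0865), 123.45, tolerance = 1e-12)
})

test_that("insulin costing reproduces the published annual requirement", {
  ins <- insulin_annual_cost(65.45, 0.1)
  expect_equal(ins$daily_iu, 6.545)
  expect_equal(ins$annual_iu, 2388.925)
  expect_equal(insulin_annual_cost(65.45, 0.1, 2.12)$annual_mxn,
               2388.925 * 2.12)
  expect_equal(insulin_annual_cost(65.45, 0)$annual_mxn, 0)
})

test_that("therapy costs and pump amortization arithmetic", {
  tbl <- cost_table()
  expect_equal(therapy_annual_cost("CSII", tbl), 53568)
  expect_equal(therapy_annual_cost("MDI", tbl), 22884.97)
  # pump replaced every 4 years: 20 undiscounted years = 5 pump purchases
  pump_price <- 4 * (53568 - 10000) # any split: price = 4 * annual share
  annual_pump <- pump_price / 4
  expect_equal(annual_pump * 20, 5 * pump_price)
})

test_that("weighted costs require shares summing to one", {
  expect_equal(weighted_cost(data.frame(cost = c(100, 200), share = c(0.5, 0.5))), 150)
  expect_equal(weighted_cost(data.frame(cost = 42, share = 1)), 42)
  pd <- weighted_cost(data.frame(cost = c(1000, 2000), share = c(0.54, 0.46)))
  expect_true(pd > 1000 && pd < 2000)
  expect_error(weighted_cost(data.frame(cost = c(1, 2), share = c(0.5, 0.6))),
               "sum to 1")
})

test_that("human-capital indirect costs respect the working-age window", {
  expect_equal(indirect_cost(65, "male", 100), 0)
  expect_equal(indirect_cost(17, "female", 100), 0)
  expect_equal(indirect_cost(40, "male", 10), 3337.60)
  expect_equal(indirect_cost(40, "female", 255), 74684.40)
  # days cap at the working year
  expect_equal(indirect_cost(40, "female", 400), 74684.40)
  expect_equal(indirect_cost(60, "male", 10), 0) # retirement is exclusive
  expect_error(indirect_cost(40, "male", -1), ">= 0")
})

test_that("per-cycle direct costs are additive and match the published unit costs", {
  # therapy-only MDI year
  c0 <- annual_direct_cost("MDI", medications = character(0),
                           screenings = character(0))
  expect_equal(unname(c0["total"]), 22884.97)
  # one severe hypoglycemic event adds its published cost
  c1 <- annual_direct_cost("MDI", events = c(severe_hypo = 1),
                           screenings = character(0))
  expect_equal(unname(c1["total"] - c0["total"]), 37000.53)
  expect_equal(unname(c1["hypoglycemia"]), 37000.53)
  # categories always sum to the total
  c2 <- annual_direct_cost("CSII",
                           incident = c("myocardial_infarction", "cataract"),
                           prevalent = c("neuropathy", "hemodialysis", "healed_ulcer"),
                           events = c(severe_hypo = 2, minor_hypo = 1,
                                      ketoacidosis = 1),
                           medications = c("statins", "ace_inhibitors"))
  expect_equal(unname(c2["total"]), sum(c2[names(c2) != "total"]))
  expect_equal(unname(c2["renal"]), 351393.12)
  expect_equal(unname(c2["cardiovascular"]), 267057.59)
  # monotone in event counts
  c3 <- annual_direct_cost("CSII",
                           incident = c("myocardial_infarction", "cataract"),
                           prevalent = c("neuropathy", "hemodialysis", "healed_ulcer"),
                           events = c(severe_hypo = 3, minor_hypo = 1,
                                      ketoacidosis = 1),
                           medications = c("statins", "ace_inhibitors"))
  expect_gt(c3["total"], c2["total"])
  expect_error(annual_direct_cost("MDI", incident = "unknown_thing"),
               "not in cost table")
})

test_that("vectorized costing agrees with the per-cycle calculator", {
  co <- generate_cohort(default_imss_spec(n = 40, seed = 13))
  sim <- simulate_arm(co, disease_params(), treatment_effects(), "MDI",
                      horizon_years = 12, seed = 71)
  tbl <- cost_table()
  cc <- cost_cycles(sim, tbl)
  total_mat <- Reduce(`+`, cc)
  comps <- colnames(sim$onset)
  tinfo <- sim$params$complications
  ly <- life_years(sim)
  for (i in c(1, 7, 19, 33)) {
    for (t in c(1, 3, 12)) {
      if (t > ly[i]) {
        expect_equal(total_mat[i, t], 0)
        next
      }
      on <- sim$onset[i, ]
      incident <- comps[!is.na(on) & on == t]
      prev_names <- comps[!is.na(on) & on < t]
      mapped_prev <- character(0)
      for (cp in prev_names) {
        if (cp == "end_stage_renal_disease") {
          mapped_prev <- c(mapped_prev, sim$modality[i])
        } else if (isTRUE(tinfo$transient[match(cp, tinfo$name)]) &&
                   cp != "gangrene") {
          mapped_prev <- c(mapped_prev, "healed_ulcer")
        } else {
          mapped_prev <- c(mapped_prev, cp)
        }
      }
      incident <- vapply(incident, function(cp)
        if (cp == "end_stage_renal_disease") sim$modality[i] else cp, "")
      meds <- c("ace_inhibitors", "statins", "aspirin")[
        c(co$med_ace_inhibitors[i], co$med_statins[i], co$med_aspirin[i])]
      if (co$comp_depression[i]) meds <- c(meds, "anti_depression")
      events <- vapply(c("severe_hypo", "minor_hypo", "ketoacidosis",
                         "lactic_acidosis", "edema"),
                       function(ev) sim$acute[[ev]][i, t], numeric(1))
      fatal_stroke <- !is.na(sim$death_cause[i]) &&
        sim$death_cause[i] == "stroke" && !is.na(sim$death_cycle[i]) &&
        sim$death_cycle[i] == t
      ref <- annual_direct_cost("MDI", incident = unname(incident),
                                prevalent = mapped_prev, events = events,
                                medications = meds, table = tbl,
                                fatal_stroke = fatal_stroke)
      expect_equal(total_mat[i, t], unname(ref["total"]), tolerance = 1e-8)
    }
  }
})

test_that("indirect cost cycles value disability days only in working ages", {
  co <- generate_cohort(point_spec(10, seed = 14, age = 55))
  sim <- simulate_arm(co, toy_params(q = 0,
                                     complications = one_complication(hazard = 1e9)),
                      null_effects(), "MDI", 10, seed = 81)
  dur <- disability_durations(neuropathy = 20)
  im <- indirect_cycles(sim, dur, salary_table())
  # onset in cycle 1 at age 55 (female since point_spec male_frac = 0)
  expect_equal(im[1, 1], 20 * 292.88)
  expect_true(all(im[, 2:10] == 0)) # no further onsets
  # same patients aged past retirement accrue nothing
  co2 <- generate_cohort(point_spec(10, seed = 14, age = 61))
  sim2 <- simulate_arm(co2, toy_params(q = 0,
                                       complications = one_complication(hazard = 1e9)),
                       null_effects(), "MDI", 10, seed = 81)
  expect_true(all(indirect_cycles(sim2, dur) == 0))
  expect_error(disability_durations(bogus = 3), "unknown")
})
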