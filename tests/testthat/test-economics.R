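test_that("discount factors use the first-cycle-undiscounted convention", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(5, 0), 1)
  expect_equal(discount_factor(1, 0.05), 1 / 1.05)
  expect_equal(discount_factor(1, 0.05), 0.952381, tolerance = 1e-6)
  expect_error(discount_factor(-1, 0.05), ">= 0")
  # 10-cycle unit annuity at 5%
  expect_equal(sum(discount_factor(0:9, 0.05)), 8.1078, tolerance = 1e-4)
})

test_that("aggregation reproduces closed-form annuities and zero-rate identities", {
  # deterministic survival for exactly 10 cycles, unit treatment cost
  co <- generate_cohort(point_spec(5, seed = 21, baseline_severe_hypo_rate = 0))
  p <- toy_params(q = 0)
  sim <- simulate_arm(co, p, null_effects(), "MDI", 10, seed = 1)
  tbl <- cost_table(overrides = list(
    mdi_annual = 1,
    screening = c(microalbuminuria = 0, gross_proteinuria = 0,
                  retinopathy = 0, depression = 0)
  ))
  u1 <- utility_table(baseline = 1)
  agg <- aggregate_arm(sim, discount_spec(0.05, 0.05), tbl, u1)
  expect_equal(agg$total_cost, 8.1078, tolerance = 1e-4)
  expect_equal(agg$total_cost_undisc, 10)
  # rate 0: discounted equals undiscounted; utility 1: QALYs equal life-years
  agg0 <- aggregate_arm(sim, discount_spec(0, 0), tbl, u1)
  expect_equal(agg0$total_cost, agg0$total_cost_undisc)
  expect_equal(agg0$qalys, agg0$life_years)
  expect_equal(agg0$life_years, 10)
  # positive rates never increase totals
  expect_lte(agg$qalys, agg0$qalys)
  expect_lte(agg$total_cost, agg0$total_cost)
  # single patient alive 1 cycle at baseline utility accrues 0.785 QALYs
  sim1 <- simulate_arm(co, p, null_effects(), "MDI", 1, seed = 1)
  agg1 <- aggregate_arm(sim1, discount_spec(0.05, 0.05))
  expect_equal(agg1$qalys, 0.785)
})

test_that("ICER carries dominance semantics and the break-even identity", {
  r <- icer(293600, 0.614)
  expect_equal(r$status, "ratio")
  expect_equal(r$value, 293600 / 0.614)
  expect_equal(r$value * 0.614, 293600, tolerance = 1e-9)
  expect_equal(icer(-1, 1)$status, "dominant")
  expect_equal(icer(1, -1)$status, "dominated")
  expect_equal(icer(1, 0)$status, "dominated")
  expect_equal(icer(-1, -1)$status, "undefined")
  # NMB: zero at the ICER, -deltaC at wtp 0
  expect_equal(nmb(293600, 0.614, r$value), 0, tolerance = 1e-9)
  expect_equal(nmb(293600, 0.614, 0), -293600)
  expect_lt(nmb(293600, 0.614, 459000), 0) # above the 3-GDP threshold
  expect_equal(nmb(293600, 0.614, 459000), 459000 * 0.614 - 293600)
})

test_that("the acceptability curve matches a Gaussian oracle and is monotone", {
  # synthetic runner: delta cost ~ N(1, 1), delta effect 0.01 exactly;
  # at wtp = 100 the NMB is 1 - deltaC, so P(cost-effective) = Phi(0) = 0.5
  runner <- function(i, n_inner, seed) {
    withr::with_seed(seed, list(delta_cost = rnorm(1, 1, 1),
                                delta_effect = 0.01))
  }
  curve <- ceac(runner, n_outer = 4000, n_inner = 1,
                wtp_grid = seq(0, 400, by = 50), seed = 5)
  p100 <- curve$probability[curve$wtp == 100]
  expect_lt(abs(p100 - 0.5), 3 * sqrt(0.25 / 4000))
  # all effects positive: monotone non-decreasing in WTP
  expect_true(all(diff(curve$probability) >= 0))
  # limits: certain at huge wtp, impossible below the cost support
  expect_gt(curve$probability[curve$wtp == 400], 0.95)
})

test_that("degenerate second-order uncertainty yields a step curve at the ICER", {
  runner <- function(i, n_inner, seed) list(delta_cost = 100, delta_effect = 0.01)
  curve <- ceac(runner, n_outer = 10, n_inner = 1,
                wtp_grid = seq(0, 20000, by = 1000), seed = 1)
  expect_true(all(curve$probability %in% c(0, 1)))
  expect_equal(curve$probability[curve$wtp <= 10000], rep(0, 11))
  expect_equal(curve$probability[curve$wtp > 10000], rep(1, 10))
})

test_that("the acceptability curve is reproducible given a seed", {
  runner <- function(i, n_inner, seed) {
    withr::with_seed(seed, list(delta_cost = rnorm(1, 1, 1), delta_effect = 0.01))
  }
  c1 <- ceac(runner, n_outer = 50, n_inner = 1, wtp_grid = c(0, 100), seed = 9)
  c2 <- ceac(runner, n_outer = 50, n_inner = 1, wtp_grid = c(0, 100), seed = 9)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(attr(c1, "draws"), attr(c2, "draws"))
})

test_that("tidy, glance and autoplot produce the reporting surfaces", {
  co <- generate_cohort(default_imss_spec(n = 60, seed = 23))
  fx <- treatment_effects()
  p <- disease_params()
  a <- aggregate_arm(simulate_arm(co, p, fx, "CSII", 20, seed = 2))
  b <- aggregate_arm(simulate_arm(co, p, fx, "MDI", 20, seed = 2))
  res <- cea_compare(a, b)
  td <- tidy(res)
  expect_true(all(c("arm", "category", "discounted", "undiscounted") %in% names(td)))
  expect_equal(nrow(td), 16) # 8 categories x 2 arms
  g <- glance(res)
  expect_equal(g$delta_cost, a$total_cost - b$total_cost)
  expect_equal(g$icer_per_qaly, res$icer_per_qaly$value)
  # per-arm category sums reproduce the totals (additivity)
  sums <- dplyr::summarise(dplyr::group_by(td, arm),
                           s = sum(discounted))
  expect_equal(sort(sums$s), sort(c(a$total_cost, b$total_cost)))
  curve <- structure(tibble::tibble(wtp = c(0, 1e5), probability = c(0, 1)),
                     class = c("ceac_curve", class(tibble::tibble())))
  expect_s3_class(autoplot(curve), "ggplot")
  expect_s3_class(plot_cost_breakdown(res), "ggplot")
})
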