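# Aggregation of simulated trajectories into discounted costs, life-years
# and QALYs; ICER/NMB computation and the cost-effectiveness acceptability
# curve. Discounting uses the cycle-start convention: the first simulated
# year (cycle index 0) is undiscounted, cycle t carries (1 + r)^-t.

#' Discount specification
#'
#' @param rate_costs,rate_effects annual discount proportions (>= 0);
#'   both default to the 5% base-case rate.
#' @return object of class `discount_spec`.
#' @export
discount_spec <- function(rate_costs = 0.05, rate_effects = 0.05) {
  if (rate_costs < 0 || rate_effects < 0) abort("discount rates must be >= 0")
  structure(list(rate_costs = rate_costs, rate_effects = rate_effects),
            class = "discount_spec")
}

#' Discount factor for a cycle index
#'
#' `(1 + rate)^(-t)` with the first cycle (t = 0) undiscounted.
#'
#' @param t_years integer cycle index (0-based; vectorized).
#' @param rate annual discount rate.
#' @return discount factor.
#' @export
#' @examples
#' discount_factor(0, 0.05) # 1
#' discount_factor(1, 0.05) # 0.952381
discount_factor <- function(t_years, rate) {
  if (any(t_years < 0)) abort("`t_years` must be >= 0")
  (1 + rate)^(-t_years)
}

# discounted row-sum of an n x TT per-cycle matrix
disc_sum <- function(mat, rate) {
  TT <- ncol(mat)
  as.numeric(mat %*% discount_factor(seq_len(TT) - 1, rate))
}

#' Aggregate one simulated arm into per-arm totals
#'
#' Means over patients of the (discounted and undiscounted) per-cycle sums
#' of costs by category, life-years and QALYs.
#'
#' @param sim an `arm_sim` from [simulate_arm()].
#' @param disc a [discount_spec()].
#' @param cost_tbl a [cost_table()].
#' @param util_tbl a [utility_table()].
#' @param include_indirect logical; add human-capital indirect costs.
#' @param durations [disability_durations()] vector (used when
#'   `include_indirect`).
#' @param salary a [salary_table()].
#' @return object of class `arm_totals`: a list with `arm`, a `costs`
#'   tibble (category, discounted, undiscounted), and scalars
#'   `total_cost`, `indirect_cost`, `life_years`, `life_years_undisc`,
#'   `qalys`, `qalys_undisc` (discounted unless suffixed).
#' @export
aggregate_arm <- function(sim, disc = discount_spec(),
                          cost_tbl = cost_table(),
                          util_tbl = utility_table(),
                          include_indirect = FALSE,
                          durations = disability_durations(),
                          salary = salary_table()) {
  cc <- cost_cycles(sim, cost_tbl)
  costs <- bind_rows(purrr::imap(cc, function(mat, cat) {
    tibble(category = cat,
           discounted = mean(disc_sum(mat, disc$rate_costs)),
           undiscounted = mean(rowSums(mat)))
  }))
  ind_d <- 0; ind_u <- 0
  if (include_indirect) {
    im <- indirect_cycles(sim, durations, salary)
    # only alive cycles accrue
    alive <- outer(life_years(sim), seq_len(sim$horizon), ">=")
    im <- im * alive
    ind_d <- mean(disc_sum(im, disc$rate_costs))
    ind_u <- mean(rowSums(im))
  }
  um <- utility_cycles(sim, util_tbl)
  alive_mat <- outer(life_years(sim), seq_len(sim$horizon), ">=") * 1
  structure(
    list(arm = sim$arm,
         n = sim$n,
         costs = costs,
         total_cost = sum(costs$discounted) + ind_d,
         total_cost_undisc = sum(costs$undiscounted) + ind_u,
         indirect_cost = ind_d,
         indirect_cost_undisc = ind_u,
         life_years = mean(disc_sum(alive_mat, disc$rate_effects)),
         life_years_undisc = mean(rowSums(alive_mat)),
         qalys = mean(disc_sum(um, disc$rate_effects)),
         qalys_undisc = mean(rowSums(um))),
    class = "arm_totals"
  )
}

#' Incremental cost-effectiveness ratio with dominance semantics
#'
#' `delta_cost / delta_effect` when the incremental effect is positive;
#' otherwise a flag: `"dominant"` (cheaper and more effective),
#' `"dominated"` (costlier and no more effective), `"undefined"` (cheaper
#' and less effective — a ratio would mislead).
#'
#' @param delta_cost incremental cost (MXN).
#' @param delta_effect incremental effect (QALYs or life-years).
#' @return list with `value` (NA unless status is `"ratio"` or
#'   `"dominant"`) and `status`.
#' @export
#' @examples
#' icer(293600, 0.614)$value # 478175.9
icer <- function(delta_cost, delta_effect) {
  if (delta_effect > 0 && delta_cost >= 0) {
    list(value = delta_cost / delta_effect, status = "ratio")
  } else if (delta_effect > 0 && delta_cost < 0) {
    list(value = delta_cost / delta_effect, status = "dominant")
  } else if (delta_effect <= 0 && delta_cost > 0) {
    list(value = NA_real_, status = "dominated")
  } else {
    list(value = NA_real_, status = "undefined")
  }
}

#' Net monetary benefit
#'
#' `wtp * delta_effect - delta_cost`.
#'
#' @param delta_cost incremental cost (MXN).
#' @param delta_effect incremental QALYs.
#' @param wtp willingness to pay per QALY (MXN, >= 0; vectorized).
#' @return MXN.
#' @export
nmb <- function(delta_cost, delta_effect, wtp) {
  if (any(wtp < 0)) abort("`wtp` must be >= 0")
  wtp * delta_effect - delta_cost
}

#' Compare two simulated arms
#'
#' Builds the full cost-effectiveness result: per-arm totals, incremental
#' cost, QALYs and life-years, and ICERs per QALY and per life-year gained.
#'
#' @param csii,mdi `arm_totals` from [aggregate_arm()] for the CSII and MDI
#'   arms.
#' @param scenario optional scenario label.
#' @return object of class `cea_result`.
#' @export
cea_compare <- function(csii, mdi, scenario = "base_case") {
  dc <- csii$total_cost - mdi$total_cost
  dq <- csii$qalys - mdi$qalys
  dly <- csii$life_years - mdi$life_years
  structure(
    list(scenario = scenario,
         csii = csii, mdi = mdi,
         delta_cost = dc, delta_qaly = dq, delta_ly = dly,
         icer_per_qaly = icer(dc, dq),
         icer_per_lyg = icer(dc, dly)),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness result —", x$scenario, "\n")
  cat(sprintf("  CSII: cost %.0f MXN, %.3f QALYs | MDI: cost %.0f MXN, %.3f QALYs\n",
              x$csii$total_cost, x$csii$qalys, x$mdi$total_cost, x$mdi$qalys))
  cat(sprintf("  ΔC = %.0f MXN, ΔQALY = %.3f, ΔLY = %.3f\n",
              x$delta_cost, x$delta_qaly, x$delta_ly))
  iq <- x$icer_per_qaly
  if (iq$status %in% c("ratio", "dominant")) {
    cat(sprintf("  ICER = %.0f MXN/QALY (%s)\n", iq$value, iq$status))
  } else {
    cat(sprintf("  ICER: %s\n", iq$status))
  }
  invisible(x)
}

#' @method tidy cea_result
#' @export
tidy.cea_result <- function(x, ...) {
  per_arm <- bind_rows(
    mutate(x$csii$costs, arm = "CSII"),
    mutate(x$mdi$costs, arm = "MDI")
  ) %>% select("arm", "category", "discounted", "undiscounted")
  per_arm
}

#' @method glance cea_result
#' @export
glance.cea_result <- function(x, ...) {
  tibble(
    scenario = x$scenario,
    cost_csii = x$csii$total_cost, cost_mdi = x$mdi$total_cost,
    qaly_csii = x$csii$qalys, qaly_mdi = x$mdi$qalys,
    ly_csii = x$csii$life_years, ly_mdi = x$mdi$life_years,
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    delta_ly = x$delta_ly,
    icer_per_qaly = x$icer_per_qaly$value,
    icer_per_qaly_status = x$icer_per_qaly$status,
    icer_per_lyg = x$icer_per_lyg$value,
    icer_per_lyg_status = x$icer_per_lyg$status
  )
}

#' Default willingness-to-pay grid
#'
#' 0 to 600,000 MXN/QALY in 10,000-MXN steps, spanning the 1-GDP (153,000)
#' and 3-GDP (459,000) per-capita thresholds.
#'
#' @return numeric vector of WTP values (MXN per QALY).
#' @export
default_wtp_grid <- function() seq(0, 600000, by = 10000)

#' Cost-effectiveness acceptability curve
#'
#' For each of `n_outer` outer draws the `model_runner` is invoked to
#' produce one incremental (cost, effect) pair — typically by sampling
#' second-order parameter uncertainty and simulating `n_inner` patients per
#' arm under common random numbers. The probability that the intervention
#' is cost-effective at a willingness-to-pay value is the fraction of draws
#' with positive net monetary benefit.
#'
#' @param model_runner `function(draw_index, n_inner, seed)` returning a
#'   list with `delta_cost` and `delta_effect`. See [make_psa_runner()].
#' @param n_outer number of outer (parameter) draws (default 1000).
#' @param n_inner number of simulated patients per draw (default 1000),
#'   passed through to the runner.
#' @param wtp_grid willingness-to-pay grid (MXN/QALY).
#' @param seed integer; per-draw seeds are derived from it.
#' @return object of class `ceac_curve`: tibble with `wtp`, `probability`,
#'   plus attributes `draws` (tibble of the sampled increments), `n_outer`,
#'   `n_inner`.
#' @export
ceac <- function(model_runner, n_outer = 1000, n_inner = 1000,
                 wtp_grid = default_wtp_grid(), seed = 1) {
  stopifnot(n_outer >= 1, n_inner >= 1)
  sub_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max - 1, n_outer))
  draws <- purrr::map(seq_len(n_outer), function(i) {
    res <- model_runner(i, n_inner, sub_seeds[i])
    tibble(draw = i, delta_cost = res$delta_cost,
           delta_effect = res$delta_effect)
  }) %>% bind_rows()
  prob <- vapply(wtp_grid, function(w) {
    mean(nmb(draws$delta_cost, draws$delta_effect, w) > 0)
  }, numeric(1))
  out <- tibble(wtp = wtp_grid, probability = prob)
  class(out) <- c("ceac_curve", class(out))
  attr(out, "draws") <- draws
  attr(out, "n_outer") <- n_outer
  attr(out, "n_inner") <- n_inner
  out
}

#' Probabilistic-sensitivity-analysis runner over the full pipeline
#'
#' Builds the `model_runner` consumed by [ceac()]: each outer draw samples
#' the HbA1c regression coefficients from their published standard errors
#' (rate-ratio coefficients held fixed — no published uncertainty), and
#' optionally scales every unit cost by a moment-matched gamma multiplier
#' with coefficient of variation `cost_cv`; it then generates a fresh
#' cohort of `n_inner` patients from `spec` and simulates both arms with
#' common random numbers.
#'
#' @param spec a [default_imss_spec()]-style cohort specification.
#' @param params a [disease_params()] object.
#' @param coefs an [effect_coefficients()] object.
#' @param disc a [discount_spec()].
#' @param cost_tbl a [cost_table()].
#' @param util_tbl a [utility_table()].
#' @param horizon simulation horizon in years.
#' @param cost_cv coefficient of variation of the gamma cost multiplier
#'   (0 disables cost uncertainty; default 0.2).
#' @return a `function(draw_index, n_inner, seed)` for [ceac()].
#' @export
make_psa_runner <- function(spec = default_imss_spec(),
                            params = disease_params(),
                            coefs = effect_coefficients(),
                            disc = discount_spec(),
                            cost_tbl = cost_table(),
                            util_tbl = utility_table(),
                            horizon = 70, cost_cv = 0.2) {
  force(spec); force(params); force(coefs); force(disc)
  force(cost_tbl); force(util_tbl); force(horizon); force(cost_cv)
  function(draw_index, n_inner, seed) {
    withr::with_seed(seed, {
      fx <- sample_effects(coefs, baseline_hba1c = spec$hba1c_mean,
                           mdi_rate = spec$baseline_severe_hypo_rate,
                           mean_age = spec$age_mean)
      mult <- if (cost_cv > 0) {
        shape <- 1 / cost_cv^2
        stats::rgamma(1, shape = shape, rate = shape)
      } else 1
      sim_seed <- sample.int(.Machine$integer.max - 1, 1)
    })
    ctbl <- cost_tbl
    ctbl$items$event_cost <- ctbl$items$event_cost * mult
    ctbl$items$subsequent_cost <- ctbl$items$subsequent_cost * mult
    ctbl$acute <- ctbl$acute * mult
    cohort_spec <- spec
    cohort_spec$n <- n_inner
    cohort_spec$seed <- sim_seed
    cohort <- generate_cohort(cohort_spec)
    s_csii <- simulate_arm(cohort, params, fx, "CSII", horizon, seed = sim_seed)
    s_mdi <- simulate_arm(cohort, params, fx, "MDI", horizon, seed = sim_seed)
    a_csii <- aggregate_arm(s_csii, disc, ctbl, util_tbl)
    a_mdi <- aggregate_arm(s_mdi, disc, ctbl, util_tbl)
    list(delta_cost = a_csii$total_cost - a_mdi$total_cost,
         delta_effect = a_csii$qalys - a_mdi$qalys)
  }
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object a `ceac_curve`.
#' @param wtp_marks WTP thresholds drawn as dashed vertical lines (default
#'   the 1- and 3-GDP-per-capita thresholds, 153,000 and 459,000 MXN).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ceac_curve
#' @export
autoplot.ceac_curve <- function(object, wtp_marks = c(153000, 459000), ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = wtp_marks, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (MXN per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot per-arm discounted cost breakdown
#'
#' @param result a `cea_result`.
#' @return a ggplot object.
#' @export
plot_cost_breakdown <- function(result) {
  df <- tidy(result)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$discounted,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Discounted lifetime cost (MXN)",
                  fill = "Category") +
    ggplot2::theme_minimal()
}
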