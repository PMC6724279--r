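# Declarative scenario runner: base case, secondary (indirect-cost) case,
# one-way sensitivity analyses and subgroup analyses, mirroring the
# published sensitivity-analysis table layout.

subgroup_filters <- list(
  hba1c_le_9 = function(cohort) cohort$hba1c <= 9,
  hba1c_gt_9 = function(cohort) cohort$hba1c > 9,
  duration_le_10 = function(cohort) cohort$diabetes_duration <= 10,
  duration_gt_10 = function(cohort) cohort$diabetes_duration > 10
)

#' Scenario specification
#'
#' @param name scenario label.
#' @param include_indirect_costs add human-capital indirect costs.
#' @param hba1c_effect_override direct CSII-vs-MDI HbA1c change
#'   (percentage points, e.g. -0.6) bypassing the regression; `NULL` keeps
#'   the regression-derived effect.
#' @param discount_override a [discount_spec()] or `NULL`.
#' @param subgroup one of `"hba1c_le_9"`, `"hba1c_gt_9"`,
#'   `"duration_le_10"`, `"duration_gt_10"`, or `NULL` for the full cohort.
#' @param seed integer simulation seed (shared by both arms: common random
#'   numbers).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, include_indirect_costs = FALSE,
                          hba1c_effect_override = NULL,
                          discount_override = NULL, subgroup = NULL,
                          seed = 1) {
  if (!is.null(subgroup) && !subgroup %in% names(subgroup_filters)) {
    abort(paste0("unknown subgroup: ", subgroup))
  }
  if (!is.null(discount_override) && !inherits(discount_override, "discount_spec")) {
    abort("`discount_override` must be a discount_spec")
  }
  if (!is.null(hba1c_effect_override) &&
      (hba1c_effect_override < -10 || hba1c_effect_override > 10)) {
    abort("`hba1c_effect_override` outside a plausible range")
  }
  structure(list(name = name,
                 include_indirect_costs = include_indirect_costs,
                 hba1c_effect_override = hba1c_effect_override,
                 discount_override = discount_override,
                 subgroup = subgroup, seed = seed),
            class = "scenario_spec")
}

#' The default scenario suite
#'
#' Nine scenarios: base case, secondary case with indirect costs, halved
#' HbA1c benefit (-0.6), the two discount-rate combinations (3% costs + 0%
#' benefits; 7% + 7%), and the four subgroups (HbA1c at or below / above
#' 9%, diabetes duration at or below / above 10 years).
#'
#' @param seed simulation seed shared across scenarios.
#' @return list of [scenario_spec()] objects.
#' @export
default_scenario_suite <- function(seed = 1) {
  list(
    scenario_spec("base_case", seed = seed),
    scenario_spec("secondary_indirect_costs", include_indirect_costs = TRUE,
                  seed = seed),
    scenario_spec("hba1c_benefit_-0.6", hba1c_effect_override = -0.6,
                  seed = seed),
    scenario_spec("disc_3pct_costs_0pct_benefits",
                  discount_override = discount_spec(0.03, 0), seed = seed),
    scenario_spec("disc_7pct_costs_7pct_benefits",
                  discount_override = discount_spec(0.07, 0.07), seed = seed),
    scenario_spec("subgroup_hba1c_le_9", subgroup = "hba1c_le_9", seed = seed),
    scenario_spec("subgroup_hba1c_gt_9", subgroup = "hba1c_gt_9", seed = seed),
    scenario_spec("subgroup_duration_le_10", subgroup = "duration_le_10",
                  seed = seed),
    scenario_spec("subgroup_duration_gt_10", subgroup = "duration_gt_10",
                  seed = seed)
  )
}

#' Run one scenario
#'
#' Applies the subgroup filter and overrides, re-derives the treatment
#' effects from the (sub)cohort's own mean baseline HbA1c and
#' severe-hypoglycemia rate through the published regressions (so the
#' poorly-controlled subgroup receives the larger regression effect), and
#' simulates both arms under common random numbers.
#'
#' @param spec a [scenario_spec()].
#' @param cohort tibble from [generate_cohort()].
#' @param params a [disease_params()] object.
#' @param coefs an [effect_coefficients()] object.
#' @param disc default [discount_spec()] (overridden per scenario).
#' @param cost_tbl a [cost_table()].
#' @param util_tbl a [utility_table()].
#' @param horizon years (default 70).
#' @param durations [disability_durations()] for indirect-cost scenarios.
#' @param salary a [salary_table()].
#' @return a `cea_result` tagged with the scenario name.
#' @export
run_scenario <- function(spec, cohort, params = disease_params(),
                         coefs = effect_coefficients(),
                         disc = discount_spec(),
                         cost_tbl = cost_table(),
                         util_tbl = utility_table(),
                         horizon = 70,
                         durations = disability_durations(),
                         salary = salary_table()) {
  if (!inherits(spec, "scenario_spec")) abort("`spec` must be a scenario_spec")
  sub <- cohort
  if (!is.null(spec$subgroup)) {
    keep <- subgroup_filters[[spec$subgroup]](cohort)
    sub <- cohort[keep, , drop = FALSE]
    if (nrow(sub) == 0) {
      abort(paste0("subgroup `", spec$subgroup, "` selects no patients"))
    }
  }
  mean_hba1c <- mean(sub$hba1c)
  mean_rate <- mean(sub$severe_hypo_rate)
  mean_age <- mean(sub$age)
  fx <- treatment_effects(
    baseline_hba1c = min(max(mean_hba1c, 4), 20),
    mdi_rate = mean_rate, mean_age = max(mean_age, 18), coefs = coefs,
    delta_hba1c = spec$hba1c_effect_override
  )
  d <- spec$discount_override %||% disc
  s_csii <- simulate_arm(sub, params, fx, "CSII", horizon, seed = spec$seed)
  s_mdi <- simulate_arm(sub, params, fx, "MDI", horizon, seed = spec$seed)
  a_csii <- aggregate_arm(s_csii, d, cost_tbl, util_tbl,
                          include_indirect = spec$include_indirect_costs,
                          durations = durations, salary = salary)
  a_mdi <- aggregate_arm(s_mdi, d, cost_tbl, util_tbl,
                         include_indirect = spec$include_indirect_costs,
                         durations = durations, salary = salary)
  cea_compare(a_csii, a_mdi, scenario = spec$name)
}

#' Run a suite of scenarios into a report table
#'
#' One row per scenario with ICERs (MXN and USD per QALY), per-arm totals
#' and QALYs. Duplicate scenario names are suffixed uniquely.
#'
#' @param specs list of [scenario_spec()] objects (default the nine-row
#'   [default_scenario_suite()]).
#' @inheritParams run_scenario
#' @param exchange_rate MXN per USD used for the USD columns.
#' @return a tibble report.
#' @export
run_suite <- function(specs = default_scenario_suite(), cohort,
                      params = disease_params(),
                      coefs = effect_coefficients(),
                      disc = discount_spec(),
                      cost_tbl = cost_table(),
                      util_tbl = utility_table(),
                      horizon = 70,
                      durations = disability_durations(),
                      salary = salary_table(),
                      exchange_rate = 18.390) {
  if (length(specs) < 1) abort("need at least one scenario")
  nms <- vapply(specs, function(s) s$name, "")
  nms <- make.unique(nms, sep = "_")
  purrr::map2(specs, nms, function(s, nm) {
    s$name <- nm
    res <- run_scenario(s, cohort, params, coefs, disc, cost_tbl, util_tbl,
                        horizon, durations, salary)
    g <- glance(res)
    mutate(g,
           icer_per_qaly_usd = to_usd(.data$icer_per_qaly, exchange_rate),
           cost_csii_usd = to_usd(.data$cost_csii, exchange_rate),
           cost_mdi_usd = to_usd(.data$cost_mdi, exchange_rate))
  }) %>% bind_rows()
}
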