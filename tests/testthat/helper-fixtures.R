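# Shared fixtures: point-mass cohorts and toy disease configurations used
# for closed-form oracles.

# spec whose continuous traits are point masses and prevalences zero:
# every patient identical, no baseline complications
point_spec <- function(n, seed = 1, age = 32.3, hba1c = 9.2, ...) {
  prev <- default_imss_spec()$complication_prev
  prev[] <- 0
  meds <- c(ace_inhibitors = 0, statins = 0, aspirin = 0)
  default_imss_spec(
    n = n, seed = seed,
    age_mean = age, age_sd = 0,
    duration_mean = 15, duration_sd = 0,
    hba1c_mean = hba1c, hba1c_sd = 0,
    bmi_sd = 0, sbp_sd = 0, total_chol_sd = 0, hdl_sd = 0, ldl_sd = 0,
    trig_sd = 0, egfr_sd = 0, hemoglobin_sd = 0, wbc_sd = 0,
    heart_rate_sd = 0,
    male_frac = 0, smoking_frac = 0, alcohol_frac = 0,
    complication_prev = prev, med_prev = meds,
    ...
  )
}

empty_complications <- function() {
  tibble::tibble(name = character(0), baseline_hazard = numeric(0),
                 rr_per_pct = numeric(0), predecessor = character(0),
                 fatality_prob = numeric(0), transient = logical(0))
}

one_complication <- function(name = "neuropathy", hazard = 0.1, rr = 1,
                             fatality = 0, transient = FALSE) {
  tibble::tibble(name = name, baseline_hazard = hazard, rr_per_pct = rr,
                 predecessor = NA_character_, fatality_prob = fatality,
                 transient = transient)
}

# params with no complications, constant mortality q and no acute events
toy_params <- function(q = 0, complications = empty_complications(), ...) {
  disease_params(complications = complications,
                 mortality = constant_mortality(q),
                 minor_hypo_rate = 0, ketoacidosis_rate = 0,
                 lactic_acidosis_rate = 0, edema_rate = 0, ...)
}
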