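# Synthetic cohort generation matched to the published IMSS baseline table.
#
# Marginals are sampled independently (only univariate summaries are
# published): continuous traits from truncated normals, triglycerides from a
# moment-matched log-normal (SD > mean makes a normal untenable), binary
# traits from Bernoulli draws.

# vocabulary of pre-existing complications (baseline prevalence rows)
baseline_complications <- c(
  "angina", "myocardial_infarction", "atrial_fibrillation",
  "left_ventricular_hypertrophy", "congestive_heart_failure",
  "peripheral_vascular_disease", "microalbuminuria", "gross_proteinuria",
  "end_stage_renal_disease", "kidney_transplant", "background_retinopathy",
  "proliferative_retinopathy", "macular_edema", "severe_visual_loss",
  "neuropathy", "uninfected_ulcer", "infected_ulcer", "amputation",
  "depression"
)

baseline_medications <- c("ace_inhibitors", "statins", "aspirin")

#' Cohort specification
#'
#' Bundles the marginal distributions from which a synthetic cohort is drawn:
#' means and SDs of demographics and biomarkers, Bernoulli prevalences of
#' pre-existing complications and medications, and the baseline severe
#' hypoglycemia rate. `default_imss_spec()` returns the specification
#' populated with the IMSS type 1 diabetes cohort baseline table (n = 192):
#' 29.2% male, age 32.3 (10.8) years, diabetes duration 18.5 (10.8) years,
#' HbA1c 9.2% (2.2), and a severe hypoglycemic event rate of 22.4 episodes
#' per 100 patient-years.
#'
#' The eGFR row of the source table prints a mean (58.1) with no SD; the
#' default SD of 20 ml/min/1.73m2 is this package's own documented choice.
#'
#' @param n number of patients to generate (default 192, the source cohort).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @param ... named overrides of any spec field.
#' @return an object of class `cohort_spec` (a named list).
#' @export
#' @examples
#' spec <- default_imss_spec()
#' spec$hba1c_mean        # 9.2
#' spec$male_frac         # 0.292
#' spec$baseline_severe_hypo_rate # 22.4
default_imss_spec <- function(n = 192, seed = NULL, ...) {
  spec <- list(
    n = n,
    seed = seed,
    male_frac = 0.292,
    age_mean = 32.3, age_sd = 10.8,
    duration_mean = 18.5, duration_sd = 10.8,
    hba1c_mean = 9.2, hba1c_sd = 2.2,
    bmi_mean = 25.1, bmi_sd = 4.3,
    sbp_mean = 107.0, sbp_sd = 15.3,
    total_chol_mean = 179.7, total_chol_sd = 46.8,
    hdl_mean = 51.9, hdl_sd = 16.6,
    ldl_mean = 100.9, ldl_sd = 35.9,
    trig_mean = 145.7, trig_sd = 185.2,
    egfr_mean = 58.1, egfr_sd = 20,
    hemoglobin_mean = 14.1, hemoglobin_sd = 2.3,
    wbc_mean = 7.4, wbc_sd = 2.3,
    heart_rate_mean = 78.1, heart_rate_sd = 10.6,
    smoking_frac = 0.099,
    alcohol_frac = 0.115,
    complication_prev = c(
      angina = 0.026, myocardial_infarction = 0.005,
      atrial_fibrillation = 0.005, left_ventricular_hypertrophy = 0.034,
      congestive_heart_failure = 0.011, peripheral_vascular_disease = 0.026,
      microalbuminuria = 0.167, gross_proteinuria = 0.161,
      end_stage_renal_disease = 0.083, kidney_transplant = 0.073,
      background_retinopathy = 0.219, proliferative_retinopathy = 0.120,
      macular_edema = 0.114, severe_visual_loss = 0.068,
      neuropathy = 0.302, uninfected_ulcer = 0.010, infected_ulcer = 0.010,
      amputation = 0.021, depression = 0.057
    ),
    med_prev = c(ace_inhibitors = 0.593, statins = 0.255, aspirin = 0.057),
    baseline_severe_hypo_rate = 22.4
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown) > 0) {
    abort(paste0("unknown cohort_spec field(s): ", paste(unknown, collapse = ", ")))
  }
  spec[names(dots)] <- dots
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec")
  chk <- function(ok, field, what) {
    if (!isTRUE(all(ok))) abort(paste0("invalid cohort_spec: `", field, "` ", what))
  }
  chk(is.numeric(spec$n) && length(spec$n) == 1 && spec$n >= 0 &&
        spec$n == floor(spec$n), "n", "must be a non-negative integer")
  props <- c(male_frac = spec$male_frac, smoking_frac = spec$smoking_frac,
             alcohol_frac = spec$alcohol_frac, spec$complication_prev,
             spec$med_prev)
  for (nm in names(props)) {
    chk(is.finite(props[[nm]]) && props[[nm]] >= 0 && props[[nm]] <= 1,
        nm, "must be a proportion in [0, 1]")
  }
  sds <- grep("_sd$", names(spec), value = TRUE)
  for (nm in sds) chk(is.finite(spec[[nm]]) && spec[[nm]] >= 0, nm, "must be >= 0")
  chk(spec$baseline_severe_hypo_rate >= 0, "baseline_severe_hypo_rate",
      "must be >= 0")
  miss <- setdiff(baseline_complications, names(spec$complication_prev))
  chk(length(miss) == 0, "complication_prev",
      paste("is missing:", paste(miss, collapse = ", ")))
  invisible(spec)
}

# truncated normal that degenerates gracefully when sd == 0. The location
# parameter is solved so the TRUNCATED mean equals `mean` (plain truncation
# would, e.g., inflate an age 32.3 (10.8) marginal by ~2 years at the
# adult lower bound of 18); the scale parameter is kept, so SDs match only
# approximately.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  mu <- mean
  if (is.finite(lower) || is.finite(upper)) {
    shift <- truncnorm::etruncnorm(a = lower, b = upper, mean = mean, sd = sd) - mean
    if (is.finite(shift) && abs(shift) > 1e-10 * max(1, abs(mean))) {
      f <- function(m) truncnorm::etruncnorm(a = lower, b = upper, mean = m, sd = sd) - mean
      mu <- tryCatch(
        stats::uniroot(f, interval = c(mean - 6 * sd, mean + 6 * sd),
                       tol = 1e-8)$root,
        error = function(e) mean
      )
    }
  }
  truncnorm::rtruncnorm(n, a = lower, b = upper, mean = mu, sd = sd)
}

# log-normal matched to (mean, sd) by moments; degenerate at sd == 0
rlnorm_moments <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  exp(rnorm(n, mu, sqrt(sigma2)))
}

#' Generate a synthetic patient cohort
#'
#' Draws `spec$n` patients with independent marginals matching the cohort
#' specification. Continuous traits come from truncated normal distributions
#' (age >= 18 for an adult cohort, HbA1c restricted to 4-20%), triglycerides
#' from a moment-matched log-normal, and binary traits from Bernoulli draws.
#' Diabetes duration is resampled until it does not exceed age. Given a
#' `seed` in the spec the cohort is bit-reproducible.
#'
#' @param spec a [default_imss_spec()]-style `cohort_spec`.
#' @return a tibble with one row per patient: demographics, biomarkers,
#'   logical `comp_*` pre-existing complication flags, `med_*` medication
#'   flags and `severe_hypo_rate` (events per 100 patient-years).
#' @export
#' @examples
#' cohort <- generate_cohort(default_imss_spec(n = 50, seed = 1))
#' dplyr::glimpse(cohort)
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- as.integer(spec$n)
  draw <- function() {
    age <- rtnorm(n, spec$age_mean, spec$age_sd, lower = 18, upper = 100)
    duration <- rtnorm(n, spec$duration_mean, spec$duration_sd, lower = 0)
    # duration cannot exceed age; resample offenders
    bad <- which(duration > age)
    tries <- 0
    while (length(bad) > 0 && tries < 1000) {
      duration[bad] <- rtnorm(length(bad), spec$duration_mean,
                              spec$duration_sd, lower = 0)
      bad <- bad[duration[bad] > age[bad]]
      tries <- tries + 1
    }
    duration <- pmin(duration, age)
    out <- tibble(
      id = seq_len(n),
      sex = ifelse(runif(n) < spec$male_frac, "male", "female"),
      age = age,
      diabetes_duration = duration,
      hba1c = rtnorm(n, spec$hba1c_mean, spec$hba1c_sd, lower = 4, upper = 20),
      bmi = rtnorm(n, spec$bmi_mean, spec$bmi_sd, lower = 12, upper = 70),
      sbp = rtnorm(n, spec$sbp_mean, spec$sbp_sd, lower = 60, upper = 260),
      total_cholesterol = rtnorm(n, spec$total_chol_mean, spec$total_chol_sd, lower = 40),
      hdl_cholesterol = rtnorm(n, spec$hdl_mean, spec$hdl_sd, lower = 5),
      ldl_cholesterol = rtnorm(n, spec$ldl_mean, spec$ldl_sd, lower = 10),
      triglycerides = rlnorm_moments(n, spec$trig_mean, spec$trig_sd),
      egfr = rtnorm(n, spec$egfr_mean, spec$egfr_sd, lower = 5, upper = 200),
      hemoglobin = rtnorm(n, spec$hemoglobin_mean, spec$hemoglobin_sd, lower = 3),
      wbc = rtnorm(n, spec$wbc_mean, spec$wbc_sd, lower = 1),
      heart_rate = rtnorm(n, spec$heart_rate_mean, spec$heart_rate_sd, lower = 30),
      smoker = runif(n) < spec$smoking_frac,
      drinker = runif(n) < spec$alcohol_frac,
      severe_hypo_rate = rep(spec$baseline_severe_hypo_rate, n)
    )
    for (comp in baseline_complications) {
      out[[paste0("comp_", comp)]] <- runif(n) < spec$complication_prev[[comp]]
    }
    for (med in baseline_medications) {
      out[[paste0("med_", med)]] <- runif(n) < spec$med_prev[[med]]
    }
    out
  }
  if (!is.null(spec$seed)) {
    withr::with_seed(spec$seed, draw())
  } else {
    draw()
  }
}

#' Summarize a cohort against its specification variables
#'
#' One row per baseline-table variable: mean and SD for continuous traits,
#' proportion for binary traits and prevalences. A single-patient cohort
#' reports `NA` SDs (flagged undefined).
#'
#' @param cohort tibble from [generate_cohort()].
#' @return tibble with columns `variable`, `type` (`"continuous"` or
#'   `"proportion"`), `mean`, `sd` (NA for proportions or when undefined).
#' @export
summarize_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    abort("cannot summarize an empty cohort")
  }
  cont <- c("age", "diabetes_duration", "hba1c", "bmi", "sbp",
            "total_cholesterol", "hdl_cholesterol", "ldl_cholesterol",
            "triglycerides", "egfr", "hemoglobin", "wbc", "heart_rate",
            "severe_hypo_rate")
  cont <- intersect(cont, names(cohort))
  rows_c <- purrr::map(cont, function(v) {
    tibble(variable = v, type = "continuous",
           mean = mean(cohort[[v]]),
           sd = if (nrow(cohort) > 1) sd(cohort[[v]]) else NA_real_)
  })
  rows_b <- list(
    tibble(variable = "male", type = "proportion",
           mean = mean(cohort$sex == "male"), sd = NA_real_)
  )
  for (v in c(names(cohort)[startsWith(names(cohort), "comp_")],
              names(cohort)[startsWith(names(cohort), "med_")],
              "smoker", "drinker")) {
    rows_b <- c(rows_b, list(tibble(variable = v, type = "proportion",
                                    mean = mean(cohort[[v]]), sd = NA_real_)))
  }
  bind_rows(bind_rows(rows_c), bind_rows(rows_b))
}

#' Write / read a cohort as flat CSV
#'
#' One row per patient, plain UTF-8 CSV with `.` decimal separator, columns
#' named by baseline-table slugs. The logical complication/medication flags
#' are stored as TRUE/FALSE.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param path file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  flags <- names(df)[startsWith(names(df), "comp_") | startsWith(names(df), "med_")]
  for (v in c(flags, intersect(c("smoker", "drinker"), names(df)))) {
    df[[v]] <- as.logical(df[[v]])
  }
  as_tibble(df)
}

#' Serialize / load a cohort specification
#'
#' @param spec a `cohort_spec`.
#' @param path YAML (or JSON, by extension) file path.
#' @export
write_cohort_spec <- function(spec, path) {
  validate_cohort_spec(spec)
  x <- unclass(spec)
  x$complication_prev <- as.list(x$complication_prev)
  x$med_prev <- as.list(x$med_prev)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  x$complication_prev <- unlist(x$complication_prev)
  x$med_prev <- unlist(x$med_prev)
  base <- default_imss_spec()
  base[names(x)] <- x
  validate_cohort_spec(base)
  base
}
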