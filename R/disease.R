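# Annual-cycle patient-level microsimulation of diabetes complications.
#
# Structural stand-in for a multi-sub-model Markov microsimulation: each
# complication is an annual-hazard process with an optional predecessor
# prerequisite, HbA1c-dependent hazard scaling h * rr^(HbA1c - ref), an
# optional in-cycle fatality probability, Poisson acute events, and a
# tabulated background-mortality life table.
#
# IMPORTANT: the default hazards, relative risks, fatality probabilities and
# life table below are SYNTHETIC values of plausible magnitude chosen by
# this package. The transition probabilities of the proprietary CORE
# Diabetes Model are not published and are not reproduced here.
#
# Common random numbers: all stochastic inputs are pre-drawn with fixed
# dimensions (one uniform per patient/cycle/complication channel, one
# fatality uniform per patient/complication, one exponential threshold per
# patient for background mortality, one uniform per patient/cycle per acute
# event type). Two arms simulated with the same seed therefore share every
# draw, which makes null effects cancel exactly and hazard reductions
# monotone in onset times.

simulated_complications <- c(
  "background_retinopathy", "proliferative_retinopathy", "macular_edema",
  "severe_visual_loss", "cataract", "microalbuminuria", "gross_proteinuria",
  "end_stage_renal_disease", "neuropathy", "uninfected_ulcer",
  "infected_ulcer", "gangrene", "amputation", "angina",
  "myocardial_infarction", "congestive_heart_failure", "stroke",
  "peripheral_vascular_disease"
)

acute_event_types <- c("severe_hypo", "minor_hypo", "ketoacidosis",
                       "lactic_acidosis", "edema")

#' Default complication definitions (synthetic parameters)
#'
#' One row per simulated complication: annual baseline hazard at the
#' reference HbA1c, relative risk per percentage point of HbA1c above the
#' reference, optional predecessor state, probability that an incident
#' event is fatal within its cycle, and whether the state is transient
#' (foot ulcers and gangrene are active in their onset cycle only, then
#' count as healed). The numbers are this package's own synthetic defaults
#' of plausible magnitude, not values from any proprietary model; override
#' them via [disease_params()] or a YAML config.
#'
#' @return tibble with columns `name`, `baseline_hazard`, `rr_per_pct`,
#'   `predecessor`, `fatality_prob`, `transient`.
#' @export
default_complications <- function() {
  tibble(
    name = simulated_complications,
    baseline_hazard = c(0.050, 0.035, 0.020, 0.030, 0.012, 0.045, 0.040,
                        0.035, 0.045, 0.030, 0.250, 0.080, 0.120, 0.008,
                        0.009, 0.007, 0.008, 0.008),
    rr_per_pct = c(1.13, 1.13, 1.13, 1.10, 1.05, 1.12, 1.12, 1.10, 1.11,
                   1.10, 1.05, 1.05, 1.05, 1.08, 1.08, 1.08, 1.08, 1.08),
    predecessor = c(NA, "background_retinopathy", "background_retinopathy",
                    "proliferative_retinopathy", NA, NA, "microalbuminuria",
                    "gross_proteinuria", NA, "neuropathy",
                    "uninfected_ulcer", "infected_ulcer", "uninfected_ulcer",
                    NA, NA, NA, NA, NA),
    fatality_prob = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.15, 0.08, 0,
                      0.20, 0.10, 0.25, 0),
    transient = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE)
  )
}

#' Default background-mortality life table (synthetic)
#'
#' Annual death probabilities by age (18-110) and sex from a Gompertz form
#' `q(age) = min(1, 0.002 * exp(0.07 * (age - 20)))` with a male/female
#' multiplier of 1.2 / 0.85 and q forced to 1 at age 110 so that every
#' simulated lifetime terminates. A synthetic stand-in of plausible
#' magnitude for an elevated-mortality type 1 diabetes population.
#'
#' @return tibble with columns `age`, `male`, `female`.
#' @export
default_mortality <- function() {
  age <- 18:110
  base <- pmin(1, 0.002 * exp(0.07 * (age - 20)))
  out <- tibble(age = age,
                male = pmin(1, base * 1.2),
                female = pmin(1, base * 0.85))
  out$male[age >= 110] <- 1
  out$female[age >= 110] <- 1
  out
}

#' Constant background mortality (for closed-form checks)
#'
#' @param q annual death probability applied at every age, both sexes.
#' @return a life-table tibble as in [default_mortality()].
#' @export
constant_mortality <- function(q) {
  age <- 18:110
  tibble(age = age, male = rep(q, length(age)), female = rep(q, length(age)))
}

#' Disease-progression parameters
#'
#' Container for everything the microsimulation consumes besides the cohort
#' and the treatment effects: the reference HbA1c at which baseline hazards
#' apply, the complication definitions, the background-mortality life
#' table, arm-independent acute-event rates, and the dialysis/transplant
#' modality split for incident end-stage renal disease.
#'
#' @param reference_hba1c percent; hazards apply unscaled at this HbA1c
#'   (default 9.2, the cohort baseline, so the MDI arm runs at baseline
#'   hazards).
#' @param complications tibble as [default_complications()].
#' @param mortality life-table tibble as [default_mortality()]; must cover
#'   ages 18-110.
#' @param minor_hypo_rate,ketoacidosis_rate,lactic_acidosis_rate,edema_rate
#'   events per 100 patient-years, equal across arms.
#' @param esrd_modality_shares named proportions (summing to 1) over
#'   `hemodialysis`, `peritoneal_dialysis`, `transplant` assigned at
#'   incident end-stage renal disease.
#' @return object of class `disease_params`.
#' @export
disease_params <- function(reference_hba1c = 9.2,
                           complications = default_complications(),
                           mortality = default_mortality(),
                           minor_hypo_rate = 30,
                           ketoacidosis_rate = 4,
                           lactic_acidosis_rate = 0.2,
                           edema_rate = 2,
                           esrd_modality_shares = c(hemodialysis = 0.5,
                                                    peritoneal_dialysis = 0.5,
                                                    transplant = 0)) {
  complications <- as_tibble(complications)
  stopifnot(all(c("name", "baseline_hazard", "rr_per_pct", "predecessor",
                  "fatality_prob", "transient") %in% names(complications)))
  if (any(complications$baseline_hazard < 0)) abort("hazards must be >= 0")
  if (any(complications$rr_per_pct <= 0)) abort("rr_per_pct must be > 0")
  if (any(complications$fatality_prob < 0 | complications$fatality_prob > 1)) {
    abort("fatality_prob must lie in [0, 1]")
  }
  pred <- complications$predecessor
  known <- is.na(pred) | pred %in% complications$name
  if (!all(known)) abort("predecessor names must be defined complications")
  # predecessors must appear before their successors (acyclic by order)
  idx <- match(pred, complications$name)
  if (any(!is.na(idx) & idx >= seq_len(nrow(complications)))) {
    abort("complications must be ordered so predecessors come first")
  }
  mortality <- as_tibble(mortality)
  if (!all(18:110 %in% mortality$age)) abort("mortality table must cover ages 18-110")
  if (any(mortality$male < 0 | mortality$male > 1 |
          mortality$female < 0 | mortality$female > 1)) {
    abort("mortality probabilities must lie in [0, 1]")
  }
  if (abs(sum(esrd_modality_shares) - 1) > 1e-8) {
    abort("esrd_modality_shares must sum to 1")
  }
  structure(
    list(reference_hba1c = reference_hba1c,
         complications = complications,
         mortality = mortality,
         acute_rates = c(minor_hypo = minor_hypo_rate,
                         ketoacidosis = ketoacidosis_rate,
                         lactic_acidosis = lactic_acidosis_rate,
                         edema = edema_rate),
         esrd_modality_shares = esrd_modality_shares),
    class = "disease_params"
  )
}

#' Serialize / load disease parameters as YAML
#'
#' @param params a [disease_params()] object.
#' @param path YAML file path.
#' @export
write_disease_params <- function(params, path) {
  x <- list(
    reference_hba1c = params$reference_hba1c,
    complications = lapply(seq_len(nrow(params$complications)), function(i) {
      r <- as.list(params$complications[i, ])
      r$predecessor <- if (is.na(r$predecessor)) NULL else r$predecessor
      r
    }),
    mortality = as.list(params$mortality),
    acute_rates = as.list(params$acute_rates),
    esrd_modality_shares = as.list(params$esrd_modality_shares)
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_disease_params
#' @export
read_disease_params <- function(path) {
  x <- yaml::read_yaml(path)
  comps <- bind_rows(lapply(x$complications, function(r) {
    tibble(name = r$name, baseline_hazard = r$baseline_hazard,
           rr_per_pct = r$rr_per_pct,
           predecessor = r$predecessor %||% NA_character_,
           fatality_prob = r$fatality_prob, transient = r$transient)
  }))
  disease_params(
    reference_hba1c = x$reference_hba1c,
    complications = comps,
    mortality = as_tibble(x$mortality),
    minor_hypo_rate = x$acute_rates$minor_hypo,
    ketoacidosis_rate = x$acute_rates$ketoacidosis,
    lactic_acidosis_rate = x$acute_rates$lactic_acidosis,
    edema_rate = x$acute_rates$edema,
    esrd_modality_shares = unlist(x$esrd_modality_shares)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' HbA1c-adjusted hazard
#'
#' Log-linear hazard scaling: `h_ref * rr^(hba1c - ref)`. Convert to an
#' annual cycle probability with [hazard_to_prob()].
#'
#' @param h_ref annual hazard at the reference HbA1c (>= 0).
#' @param rr relative risk per percentage point of HbA1c (> 0).
#' @param hba1c current HbA1c, percent.
#' @param ref reference HbA1c, percent.
#' @return adjusted annual hazard.
#' @export
#' @examples
#' adjust_hazard(0.02, 1.1, 11.2, 9.2) # 0.0242
adjust_hazard <- function(h_ref, rr, hba1c, ref) {
  if (any(h_ref < 0)) abort("`h_ref` must be >= 0")
  if (any(rr <= 0)) abort("`rr` must be > 0")
  h_ref * rr^(hba1c - ref)
}

#' @rdname adjust_hazard
#' @param h annual hazard.
#' @export
hazard_to_prob <- function(h) 1 - exp(-h)

# lookup annual death probability for integer ages (clamped to table range)
mortality_prob <- function(mortality, age, sex) {
  a <- pmin(pmax(floor(age), min(mortality$age)), max(mortality$age))
  i <- match(a, mortality$age)
  ifelse(sex == "male", mortality$male[i], mortality$female[i])
}

# map baseline comp_* flags of a cohort onto the simulated state vocabulary:
# returns list(onset = matrix of 0/NA, modality = chr vec)
baseline_states <- function(cohort, comps) {
  n <- nrow(cohort)
  onset <- matrix(NA_integer_, n, length(comps), dimnames = list(NULL, comps))
  for (cp in comps) {
    col <- paste0("comp_", cp)
    if (col %in% names(cohort)) onset[cohort[[col]], cp] <- 0L
  }
  modality <- rep(NA_character_, n)
  if ("end_stage_renal_disease" %in% comps) {
    esrd <- !is.na(onset[, "end_stage_renal_disease"])
    modality[esrd] <- "hemodialysis"  # provisional; dialysis split applied below
    if ("comp_kidney_transplant" %in% names(cohort)) {
      tx <- cohort$comp_kidney_transplant
      onset[tx, "end_stage_renal_disease"] <- 0L
      modality[tx] <- "transplant"
    }
  }
  list(onset = onset, modality = modality)
}

assign_modality <- function(u, shares) {
  cuts <- cumsum(shares) / sum(shares)
  names(shares)[findInterval(u, c(0, cuts), rightmost.closed = TRUE,
                             all.inside = TRUE)]
}

#' Simulate one treatment arm over the time horizon
#'
#' Steps every patient through annual cycles until death or the horizon.
#' Each cycle draws complication onsets (HbA1c-adjusted probability,
#' predecessor prerequisites honoured, onsets evaluated before the death
#' draw so a fatal-event year still accrues its event), Poisson acute-event
#' counts (the severe-hypoglycemia rate is arm-specific via the treatment
#' effects; other acute rates are arm-independent), and death from
#' background mortality or event fatality. HbA1c is set once to
#' baseline + the arm's HbA1c change (CSII) or baseline (MDI) and held
#' constant. Running both arms with the same `seed` yields common random
#' numbers.
#'
#' @param cohort tibble from [generate_cohort()] (needs `age`, `sex`,
#'   `hba1c`, `severe_hypo_rate` and `comp_*` flags).
#' @param params a [disease_params()] object.
#' @param effects a [treatment_effects()] object.
#' @param arm `"CSII"` or `"MDI"`.
#' @param horizon_years maximum number of annual cycles (default 70).
#' @param seed integer seed; the same seed across arms gives paired runs.
#' @return object of class `arm_sim`: baseline data, per-patient onset
#'   cycles per complication (0 = pre-existing, NA = never), death cycle and
#'   cause, ESRD modality, and per-cycle acute-event count matrices.
#' @export
simulate_arm <- function(cohort, params, effects, arm = c("CSII", "MDI"),
                         horizon_years = 70, seed = NULL) {
  arm <- match.arg(arm)
  stopifnot(horizon_years >= 1)
  n <- nrow(cohort)
  n_cyc <- as.integer(horizon_years)
  comps <- params$complications$name
  nc <- length(comps)

  hba1c <- cohort$hba1c
  if (arm == "CSII") hba1c <- pmax(4, hba1c + effects$delta_hba1c)
  hypo_rate <- cohort$severe_hypo_rate
  if (arm == "CSII") hypo_rate <- hypo_rate / effects$hypo_rate_ratio

  st <- baseline_states(cohort, comps)
  onset <- st$onset
  modality <- st$modality

  draws <- local({
    gen <- function() {
      list(
        U = array(runif(n * n_cyc * max(nc, 1)), dim = c(n, n_cyc, max(nc, 1))),
        V = matrix(runif(n * max(nc, 1)), n, max(nc, 1)),
        W = runif(n),
        E = rexp(n),
        acute = setNames(lapply(acute_event_types,
                                function(x) matrix(runif(n * n_cyc), n, n_cyc)),
                         acute_event_types)
      )
    }
    if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
  })

  # split prevalent dialysis patients across modalities using W
  if ("end_stage_renal_disease" %in% comps) {
    dial <- !is.na(onset[, match("end_stage_renal_disease", comps)]) &
      !is.na(modality) & modality == "hemodialysis"
    if (any(dial)) {
      sh <- params$esrd_modality_shares[c("hemodialysis", "peritoneal_dialysis")]
      if (sum(sh) > 0) {
        modality[dial] <- assign_modality(draws$W[dial], sh)
      }
    }
  }

  # background death cycle from one exponential threshold per patient
  cumhaz <- numeric(n)
  death_bg <- rep(NA_integer_, n)
  for (t in seq_len(n_cyc)) {
    q <- mortality_prob(params$mortality, cohort$age + t - 1, cohort$sex)
    cumhaz <- cumhaz + ifelse(q >= 1, Inf, -log(1 - q))
    hit <- is.na(death_bg) & cumhaz >= draws$E
    death_bg[hit] <- t
  }

  has <- !is.na(onset)
  pred_idx <- match(params$complications$predecessor, comps)
  fat <- params$complications$fatality_prob
  death_cycle <- rep(NA_integer_, n)
  death_cause <- rep(NA_character_, n)
  acute_counts <- setNames(lapply(acute_event_types,
                                  function(x) matrix(0L, n, n_cyc)),
                           acute_event_types)
  acute_lambda <- list(
    severe_hypo = hypo_rate / 100,
    minor_hypo = rep(params$acute_rates[["minor_hypo"]] / 100, n),
    ketoacidosis = rep(params$acute_rates[["ketoacidosis"]] / 100, n),
    lactic_acidosis = rep(params$acute_rates[["lactic_acidosis"]] / 100, n),
    edema = rep(params$acute_rates[["edema"]] / 100, n)
  )

  for (t in seq_len(n_cyc)) {
    alive <- is.na(death_cycle)
    if (!any(alive)) break
    newly_fatal <- rep(FALSE, n)
    fatal_cause <- rep(NA_character_, n)
    for (ci in seq_len(nc)) {
      elig <- alive & !has[, ci]
      if (!is.na(pred_idx[ci])) elig <- elig & has[, pred_idx[ci]]
      if (!any(elig)) next
      h <- adjust_hazard(params$complications$baseline_hazard[ci],
                         params$complications$rr_per_pct[ci],
                         hba1c, params$reference_hba1c)
      p <- hazard_to_prob(h)
      hit <- elig & draws$U[, t, ci] < p
      if (!any(hit)) next
      has[hit, ci] <- TRUE
      onset[hit, ci] <- t
      if (comps[ci] == "end_stage_renal_disease") {
        modality[hit] <- assign_modality(draws$W[hit],
                                         params$esrd_modality_shares)
      }
      if (fat[ci] > 0) {
        f <- hit & draws$V[, ci] < fat[ci]
        fatal_cause[f & !newly_fatal] <- comps[ci]
        newly_fatal <- newly_fatal | f
      }
    }
    for (ev in acute_event_types) {
      k <- qpois(draws$acute[[ev]][, t], acute_lambda[[ev]])
      k[!alive] <- 0L
      acute_counts[[ev]][, t] <- k
    }
    dies_ev <- alive & newly_fatal
    dies_bg <- alive & !dies_ev & !is.na(death_bg) & death_bg == t
    death_cycle[dies_ev] <- t
    death_cause[dies_ev] <- fatal_cause[dies_ev]
    death_cycle[dies_bg] <- t
    death_cause[dies_bg] <- "background"
  }

  structure(
    list(arm = arm, horizon = n_cyc, n = n, baseline = cohort, hba1c = hba1c,
         severe_hypo_rate = hypo_rate, onset = onset,
         death_cycle = death_cycle, death_cause = death_cause,
         modality = modality, acute = acute_counts,
         params = params, effects = effects, seed = seed),
    class = "arm_sim"
  )
}

#' Per-patient life-years of a simulated arm
#'
#' A patient alive at the start of cycle t accrues that full cycle (no
#' half-cycle correction); death in cycle t therefore yields t life-years.
#'
#' @param sim an `arm_sim`.
#' @return integer vector of life-years, one per patient.
#' @export
life_years <- function(sim) {
  ifelse(is.na(sim$death_cycle), sim$horizon, sim$death_cycle)
}

#' Mean time free of a complication
#'
#' Years from baseline to first onset, averaged over patients. Patients
#' with the complication at baseline contribute 0; patients who die or
#' reach the horizon without it contribute their observed lifetime
#' (censoring counts as time observed).
#'
#' @param sim an `arm_sim`.
#' @param complication a simulated complication name.
#' @return mean years free of the complication.
#' @export
time_free_of <- function(sim, complication) {
  ci <- match(complication, colnames(sim$onset))
  if (is.na(ci)) abort(paste0("unknown complication: ", complication))
  ly <- life_years(sim)
  t_free <- ifelse(is.na(sim$onset[, ci]), ly, pmin(sim$onset[, ci], ly))
  mean(t_free)
}

#' Complication counts per patient
#'
#' Number of distinct complications with an onset during the simulation
#' (baseline-prevalent states excluded).
#'
#' @param sim an `arm_sim`.
#' @return integer vector, one count per patient.
#' @export
complication_counts <- function(sim) {
  rowSums(!is.na(sim$onset) & sim$onset > 0)
}

#' Long-format trajectories
#'
#' One row per patient-cycle up to death/horizon: age, active chronic
#' states, incident complications and acute-event counts of the cycle.
#'
#' @param sim an `arm_sim`.
#' @return a long tibble suitable for CSV export.
#' @export
as_trajectories <- function(sim) {
  ly <- life_years(sim)
  comps <- colnames(sim$onset)
  rows <- purrr::map(seq_len(sim$n), function(i) {
    cycles <- seq_len(ly[i])
    onset_i <- sim$onset[i, ]
    tibble(
      id = sim$baseline$id[i],
      cycle = cycles,
      age = sim$baseline$age[i] + cycles - 1,
      alive_at_end = !(cycles == ly[i] & !is.na(sim$death_cycle[i])),
      incident = vapply(cycles, function(t)
        paste(comps[!is.na(onset_i) & onset_i == t], collapse = ";"), ""),
      states = vapply(cycles, function(t)
        paste(comps[!is.na(onset_i) & onset_i <= t], collapse = ";"), ""),
      severe_hypo = sim$acute$severe_hypo[i, cycles],
      minor_hypo = sim$acute$minor_hypo[i, cycles],
      ketoacidosis = sim$acute$ketoacidosis[i, cycles],
      lactic_acidosis = sim$acute$lactic_acidosis[i, cycles],
      edema = sim$acute$edema[i, cycles]
    )
  })
  bind_rows(rows)
}

#' Advance a single patient one annual cycle
#'
#' Single-patient counterpart of the vectorized engine, drawing from the
#' current RNG stream: complication onsets first (predecessors honoured,
#' HbA1c-adjusted), then Poisson acute events, then death from event
#' fatality or background mortality; age advances by one year. Stepping a
#' dead patient is a contract violation and errors.
#'
#' @param state list with `alive`, `age`, `sex`, `hba1c`,
#'   `severe_hypo_rate` (per 100 patient-years) and `complications` (named
#'   numeric vector of onset years).
#' @param params a [disease_params()] object. Treatment effects are already
#'   baked into the state's HbA1c and severe-hypoglycemia rate by
#'   [new_patient_state()].
#' @param cycle current 1-based cycle index being simulated.
#' @return updated state with `events_this_cycle` (list of incident
#'   complications and acute-event counts).
#' @export
step_patient <- function(state, params, cycle = 1) {
  if (!isTRUE(state$alive)) abort("cannot step a dead patient")
  comps <- params$complications$name
  pred <- params$complications$predecessor
  incident <- character(0)
  fatal <- FALSE
  for (ci in seq_along(comps)) {
    if (comps[ci] %in% names(state$complications)) next
    if (!is.na(pred[ci]) && !(pred[ci] %in% names(state$complications))) next
    h <- adjust_hazard(params$complications$baseline_hazard[ci],
                       params$complications$rr_per_pct[ci],
                       state$hba1c, params$reference_hba1c)
    if (runif(1) < hazard_to_prob(h)) {
      state$complications[comps[ci]] <- cycle
      incident <- c(incident, comps[ci])
      if (runif(1) < params$complications$fatality_prob[ci]) fatal <- TRUE
    }
  }
  acute <- c(severe_hypo = stats::rpois(1, state$severe_hypo_rate / 100),
             minor_hypo = stats::rpois(1, params$acute_rates[["minor_hypo"]] / 100),
             ketoacidosis = stats::rpois(1, params$acute_rates[["ketoacidosis"]] / 100),
             lactic_acidosis = stats::rpois(1, params$acute_rates[["lactic_acidosis"]] / 100),
             edema = stats::rpois(1, params$acute_rates[["edema"]] / 100))
  q <- mortality_prob(params$mortality, state$age, state$sex)
  if (fatal || runif(1) < q) state$alive <- FALSE
  state$age <- state$age + 1
  state$events_this_cycle <- list(incident = incident, acute = acute)
  state
}

#' Initial simulation state for one patient row
#'
#' Applies the arm's treatment effects (HbA1c shift, severe-hypoglycemia
#' rate division) and collects the baseline complication flags.
#'
#' @param patient one-row tibble from [generate_cohort()].
#' @param effects a [treatment_effects()] object.
#' @param arm `"CSII"` or `"MDI"`.
#' @return a state list consumable by [step_patient()].
#' @export
new_patient_state <- function(patient, effects = null_effects(),
                              arm = c("MDI", "CSII")) {
  arm <- match.arg(arm)
  comps <- character(0)
  for (cp in simulated_complications) {
    col <- paste0("comp_", cp)
    if (col %in% names(patient) && isTRUE(patient[[col]])) comps <- c(comps, cp)
  }
  onsets <- setNames(rep(0, length(comps)), comps)
  hba1c <- patient$hba1c
  rate <- patient$severe_hypo_rate
  if (arm == "CSII") {
    hba1c <- max(4, hba1c + effects$delta_hba1c)
    rate <- rate / effects$hypo_rate_ratio
  }
  list(alive = TRUE, age = patient$age, sex = patient$sex, hba1c = hba1c,
       severe_hypo_rate = rate, complications = onsets,
       events_this_cycle = NULL)
}
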