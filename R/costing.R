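# Valuation of simulated states and events in 2016 Mexican pesos, following
# the published IMSS unit-cost table and its derivation footnotes: the
# subsequent-year rule (one ninth of the event-year DRG cost), the
# 2014->2016 health-care inflation rate of 0.0865, the 18.390 MXN/USD
# exchange rate, and the human-capital indirect-cost model. MXN is the
# canonical currency everywhere; USD is derived only at reporting time.

cost_categories <- c("treatment", "management", "cardiovascular", "renal",
                     "ulcer_amputation_neuropathy", "eye", "hypoglycemia",
                     "other_acute")

#' Each-subsequent-year maintenance cost from an event-year cost
#'
#' The published subsequent-year rows equal one ninth of the event-year
#' cost, rounded to centavos (the footnote's "10% of the acute event where
#' the acute event is 90% of the total DRG" wording is reproduced by the
#' /9 arithmetic on all five printed rows, e.g. 267,057.59 -> 29,673.07 for
#' myocardial infarction).
#'
#' @param event_year_cost MXN (>= 0).
#' @return MXN rounded to two decimals.
#' @export
#' @examples
#' subsequent_year_cost(267057.59) # 29673.07
subsequent_year_cost <- function(event_year_cost) {
  if (any(event_year_cost < 0)) abort("`event_year_cost` must be >= 0")
  round(event_year_cost / 9, 2)
}

#' Inflate a 2014 DRG cost to 2016
#'
#' Single application of the health-care-specific inflation rate (0.0865).
#'
#' @param cost_2014 MXN (>= 0).
#' @param rate inflation rate (default 0.0865).
#' @return 2016 MXN.
#' @export
inflate_drg <- function(cost_2014, rate = 0.0865) {
  if (any(cost_2014 < 0)) abort("`cost_2014` must be >= 0")
  cost_2014 * (1 + rate)
}

#' Convert MXN to USD at the 2016 exchange rate
#'
#' @param mxn amount in Mexican pesos.
#' @param rate pesos per dollar (default 18.390).
#' @return USD rounded to cents.
#' @export
#' @examples
#' to_usd(53568)    # 2912.89
#' to_usd(22884.97) # 1244.42
to_usd <- function(mxn, rate = 18.390) {
  if (rate <= 0) abort("exchange rate must be > 0")
  round(mxn / rate, 2)
}

#' Annual insulin requirement and cost
#'
#' Weight-based dosing: daily IU = weight * dose, annual IU = daily * 365,
#' cost = annual IU * unit cost. At the cohort mean weight of 65.45 kg and
#' 0.1 IU/kg this reproduces the published 2,388.925 IU annual requirement.
#'
#' @param weight_kg body weight (> 0).
#' @param dose_iu_per_kg daily dose per kg (>= 0).
#' @param unit_cost_mxn_per_iu MXN per IU (default 2.12, lispro).
#' @return tibble with `daily_iu`, `annual_iu`, `annual_mxn`.
#' @export
#' @examples
#' insulin_annual_cost(65.45, 0.1)$annual_iu # 2388.925
insulin_annual_cost <- function(weight_kg, dose_iu_per_kg,
                                unit_cost_mxn_per_iu = 2.12) {
  if (any(weight_kg <= 0)) abort("`weight_kg` must be > 0")
  if (any(dose_iu_per_kg < 0)) abort("`dose_iu_per_kg` must be >= 0")
  daily <- weight_kg * dose_iu_per_kg
  annual <- daily * 365
  tibble(daily_iu = daily, annual_iu = annual,
         annual_mxn = annual * unit_cost_mxn_per_iu)
}

#' Share-weighted average cost
#'
#' `sum(cost * share)` with shares required to sum to 1 (within 1e-6), the
#' rule used for drug-class averages and the manual/automated peritoneal
#' dialysis mix.
#'
#' @param components data frame with columns `cost` and `share`.
#' @return MXN.
#' @export
weighted_cost <- function(components) {
  if (any(components$share < 0)) abort("shares must be >= 0")
  if (abs(sum(components$share) - 1) > 1e-6) abort("shares must sum to 1")
  sum(components$cost * components$share)
}

#' Unit-cost table (2016 MXN)
#'
#' All event-year / subsequent-year complication costs, therapy costs
#' (CSII 53,568.00; MDI 22,884.97 per year), acute-event costs, monthly
#' medication and per-procedure screening costs, with the cost category
#' each item reports under. Every value is the published 2016 MXN figure;
#' any entry can be overridden.
#'
#' @param overrides named list: `items` (tibble rows replacing matching
#'   `item` names), or scalar fields such as `csii_annual`, `mdi_annual`.
#' @return object of class `cost_table`.
#' @export
cost_table <- function(overrides = NULL) {
  items <- tibble::tribble(
    ~item,                        ~event_cost, ~subsequent_cost, ~category,
    "myocardial_infarction",      267057.59,   29673.07,  "cardiovascular",
    "angina",                     108136.66,   12015.18,  "cardiovascular",
    "congestive_heart_failure",   155593.67,   17288.19,  "cardiovascular",
    "stroke",                      41540.56,    4615.62,  "cardiovascular",
    "peripheral_vascular_disease", 83605.69,    9289.52,  "cardiovascular",
    "hemodialysis",               434803.79,  351393.12,  "renal",
    "peritoneal_dialysis",        301440.53,  212620.35,  "renal",
    "transplant",                 425899.73,   27466.00,  "renal",
    "background_retinopathy",          0.00,       0.00,  "eye",
    "proliferative_retinopathy",   24097.72,       0.00,  "eye",
    "macular_edema",               24097.72,       0.00,  "eye",
    "severe_visual_loss",          52652.36,     957.00,  "eye",
    "cataract",                    35895.20,     957.00,  "eye",
    "microalbuminuria",                0.00,       0.00,  "renal",
    "gross_proteinuria",               0.00,       0.00,  "renal",
    "neuropathy",                  63586.97,   37982.45,  "ulcer_amputation_neuropathy",
    "uninfected_ulcer",            32703.13,     957.00,  "ulcer_amputation_neuropathy",
    "infected_ulcer",              45010.25,     957.00,  "ulcer_amputation_neuropathy",
    "gangrene",                   118143.63,       0.00,  "ulcer_amputation_neuropathy",
    "amputation",                 157824.66,       0.00,  "ulcer_amputation_neuropathy"
  )
  tbl <- list(
    items = items,
    therapy = c(csii_annual = 53568.00, mdi_annual = 22884.97),
    stroke_death_cost = 41104.86,
    acute = c(severe_hypo = 37000.53, minor_hypo = 990.00,
              ketoacidosis = 37000.53, lactic_acidosis = 37000.53,
              edema = 990.00),
    edema_follow_up = 957.00,
    medication_monthly = c(statins = 50.59, aspirin = 0.09,
                           ace_inhibitors = 7.30, anti_depression = 981.78),
    screening = c(microalbuminuria = 97.00, gross_proteinuria = 97.00,
                  retinopathy = 316.00, depression = 957.00),
    exchange_rate_mxn_per_usd = 18.390,
    drg_inflation_2014_2016 = 0.0865
  )
  if (!is.null(overrides)) {
    for (nm in setdiff(names(overrides), "items")) {
      if (!nm %in% c(names(tbl), names(tbl$therapy))) {
        abort(paste0("unknown cost_table field: ", nm))
      }
      if (nm %in% names(tbl$therapy)) tbl$therapy[[nm]] <- overrides[[nm]]
      else tbl[[nm]] <- overrides[[nm]]
    }
    if (!is.null(overrides$items)) {
      repl <- as_tibble(overrides$items)
      for (i in seq_len(nrow(repl))) {
        j <- match(repl$item[i], tbl$items$item)
        if (is.na(j)) abort(paste0("unknown cost item: ", repl$item[i]))
        for (col in setdiff(names(repl), "item")) tbl$items[[col]][j] <- repl[[col]][i]
      }
    }
  }
  if (any(tbl$items$event_cost < 0) || any(tbl$items$subsequent_cost < 0) ||
      any(tbl$therapy < 0) || any(tbl$acute < 0)) {
    abort("costs must be >= 0")
  }
  structure(tbl, class = "cost_table")
}

#' Annual therapy cost of an arm
#'
#' CSII: insulin pump amortized over its four-year warranty plus annual
#' consumables and insulin, totalling 53,568 MXN/year by default. MDI:
#' 22,884.97 MXN/year.
#'
#' @param arm `"CSII"` or `"MDI"`.
#' @param table a [cost_table()].
#' @return MXN per year.
#' @export
therapy_annual_cost <- function(arm = c("CSII", "MDI"), table = cost_table()) {
  arm <- match.arg(arm)
  if (arm == "CSII") table$therapy[["csii_annual"]] else table$therapy[["mdi_annual"]]
}

#' Salary inputs for human-capital indirect costing
#'
#' Published IMSS inputs: first income at 18, retirement at 60, mean daily
#' salary 333.76 MXN (male) / 292.88 MXN (female), 255 working days/year.
#'
#' @param retirement_age,first_income_age years.
#' @param daily_salary_male,daily_salary_female MXN per day.
#' @param workdays_per_year days.
#' @return object of class `salary_table`.
#' @export
salary_table <- function(retirement_age = 60, first_income_age = 18,
                         daily_salary_male = 333.76,
                         daily_salary_female = 292.88,
                         workdays_per_year = 255) {
  if (!(first_income_age < retirement_age)) {
    abort("first_income_age must be below retirement_age")
  }
  if (daily_salary_male <= 0 || daily_salary_female <= 0) {
    abort("salaries must be > 0")
  }
  structure(list(retirement_age = retirement_age,
                 first_income_age = first_income_age,
                 daily_salary_male = daily_salary_male,
                 daily_salary_female = daily_salary_female,
                 workdays_per_year = workdays_per_year),
            class = "salary_table")
}

#' Disability-leave durations per complication (workdays per event-year)
#'
#' The source model's disability durations are not published; the default
#' is zero for every item, making indirect costs opt-in. Supply named
#' workday counts (complication or acute-event names) to activate them.
#'
#' @param ... named workday durations overriding the zero defaults.
#' @return named numeric vector over complications and acute events.
#' @export
disability_durations <- function(...) {
  d <- setNames(rep(0, length(simulated_complications) + length(acute_event_types)),
                c(simulated_complications, acute_event_types))
  dots <- c(...)
  if (length(dots) > 0) {
    unknown <- setdiff(names(dots), names(d))
    if (length(unknown) > 0) {
      abort(paste0("unknown disability item(s): ", paste(unknown, collapse = ", ")))
    }
    if (any(dots < 0)) abort("durations must be >= 0")
    d[names(dots)] <- dots
  }
  d
}

#' Human-capital indirect cost of disability leave
#'
#' Zero outside the working-age window [first income, retirement); inside
#' it, disability days (capped at the working year) valued at the
#' sex-specific daily salary.
#'
#' @param age years (vectorized).
#' @param sex `"male"` or `"female"` (vectorized).
#' @param disability_days workdays lost (>= 0, vectorized).
#' @param salary a [salary_table()].
#' @return MXN.
#' @export
#' @examples
#' indirect_cost(40, "male", 10)    # 3337.60
#' indirect_cost(65, "female", 255) # 0
indirect_cost <- function(age, sex, disability_days, salary = salary_table()) {
  if (any(disability_days < 0)) abort("`disability_days` must be >= 0")
  working <- age >= salary$first_income_age & age < salary$retirement_age
  daily <- ifelse(sex == "male", salary$daily_salary_male,
                  salary$daily_salary_female)
  ifelse(working, pmin(disability_days, salary$workdays_per_year) * daily, 0)
}

#' Direct cost of one patient-cycle, by category
#'
#' Therapy + management (monthly medications x 12 and annual screenings) +
#' event-year costs for this cycle's incident complications +
#' subsequent-year costs for prevalent chronic states + acute-event costs.
#' Categories sum to the total by construction.
#'
#' @param arm `"CSII"` or `"MDI"`.
#' @param incident character vector of complications incident this cycle.
#' @param prevalent character vector of chronic states present before this
#'   cycle (transient ulcer/gangrene states count as healed:
#'   use `"healed_ulcer"`); use `"hemodialysis"`, `"peritoneal_dialysis"`
#'   or `"transplant"` for end-stage renal disease.
#' @param events named counts of acute events (severe_hypo, minor_hypo,
#'   ketoacidosis, lactic_acidosis, edema).
#' @param medications character vector of medication flags (ace_inhibitors,
#'   statins, aspirin, anti_depression).
#' @param screenings character vector of screening procedures applied this
#'   cycle (defaults to the four annual screens).
#' @param table a [cost_table()].
#' @param fatal_stroke if TRUE and `"stroke"` is incident, the stroke-death
#'   DRG replaces the stroke event-year cost.
#' @return named numeric vector over cost categories plus `total`.
#' @export
annual_direct_cost <- function(arm, incident = character(0),
                               prevalent = character(0),
                               events = c(severe_hypo = 0),
                               medications = character(0),
                               screenings = c("microalbuminuria",
                                              "gross_proteinuria",
                                              "retinopathy", "depression"),
                               table = cost_table(), fatal_stroke = FALSE) {
  out <- setNames(rep(0, length(cost_categories)), cost_categories)
  out["treatment"] <- therapy_annual_cost(arm, table)
  for (m in medications) {
    if (!m %in% names(table$medication_monthly)) {
      abort(paste0("unknown medication: ", m))
    }
    out["management"] <- out["management"] + table$medication_monthly[[m]] * 12
  }
  for (s in screenings) {
    if (!s %in% names(table$screening)) abort(paste0("unknown screening: ", s))
    out["management"] <- out["management"] + table$screening[[s]]
  }
  item_cost <- function(name, col) {
    j <- match(name, table$items$item)
    if (is.na(j)) abort(paste0("event not in cost table: ", name))
    table$items[[col]][j]
  }
  for (cp in incident) {
    cat <- table$items$category[match(cp, table$items$item)]
    if (is.na(cat)) abort(paste0("event not in cost table: ", cp))
    cost <- if (cp == "stroke" && fatal_stroke) table$stroke_death_cost
            else item_cost(cp, "event_cost")
    out[cat] <- out[cat] + cost
  }
  for (cp in prevalent) {
    if (cp == "healed_ulcer") {
      out["ulcer_amputation_neuropathy"] <-
        out["ulcer_amputation_neuropathy"] + table$edema_follow_up
      next
    }
    cat <- table$items$category[match(cp, table$items$item)]
    if (is.na(cat)) abort(paste0("state not in cost table: ", cp))
    out[cat] <- out[cat] + item_cost(cp, "subsequent_cost")
  }
  for (ev in names(events)) {
    if (!ev %in% names(table$acute)) abort(paste0("unknown acute event: ", ev))
    cat <- if (ev %in% c("severe_hypo", "minor_hypo")) "hypoglycemia"
           else "other_acute"
    out[cat] <- out[cat] + events[[ev]] * table$acute[[ev]]
  }
  c(out, total = sum(out))
}

#' Per-cycle direct-cost matrices for a simulated arm
#'
#' Vectorized costing of every patient-cycle: returns one `n x horizon`
#' matrix per cost category, in MXN. Dead patient-cycles cost zero; the
#' death cycle itself still accrues (onsets are evaluated before the death
#' draw, so a fatal-event year carries its event cost).
#'
#' @param sim an `arm_sim` from [simulate_arm()].
#' @param table a [cost_table()].
#' @param screenings screening procedures applied annually to alive patients.
#' @return named list of matrices, one per cost category.
#' @export
cost_cycles <- function(sim, table = cost_table(),
                        screenings = c("microalbuminuria", "gross_proteinuria",
                                       "retinopathy", "depression")) {
  n <- sim$n; TT <- sim$horizon
  ly <- life_years(sim)
  alive <- outer(ly, seq_len(TT), ">=")  # accrues cycle t
  zero <- matrix(0, n, TT)
  out <- setNames(lapply(cost_categories, function(x) zero), cost_categories)

  out$treatment <- alive * therapy_annual_cost(sim$arm, table)

  med_annual <- rep(0, n)
  for (m in c("ace_inhibitors", "statins", "aspirin")) {
    col <- paste0("med_", m)
    if (col %in% names(sim$baseline)) {
      med_annual <- med_annual +
        sim$baseline[[col]] * table$medication_monthly[[m]] * 12
    }
  }
  if ("comp_depression" %in% names(sim$baseline)) {
    med_annual <- med_annual +
      sim$baseline$comp_depression * table$medication_monthly[["anti_depression"]] * 12
  }
  screen_annual <- sum(table$screening[screenings])
  out$management <- alive * (med_annual + screen_annual)

  comps <- colnames(sim$onset)
  tinfo <- sim$params$complications
  cycle_idx <- matrix(rep(seq_len(TT), each = n), n, TT)
  for (ci in seq_along(comps)) {
    cp <- comps[ci]
    on <- sim$onset[, ci]
    if (all(is.na(on))) next
    started <- !is.na(on) & outer(on, seq_len(TT), "<=")
    event_year <- !is.na(on) & outer(on, seq_len(TT), "==") & alive
    later_years <- started & !event_year & alive
    transient <- isTRUE(tinfo$transient[match(cp, tinfo$name)])
    if (cp == "end_stage_renal_disease") {
      for (mod in c("hemodialysis", "peritoneal_dialysis", "transplant")) {
        sel <- !is.na(sim$modality) & sim$modality == mod
        j <- match(mod, table$items$item)
        add <- event_year * sel * table$items$event_cost[j] +
          later_years * sel * table$items$subsequent_cost[j]
        out$renal <- out$renal + add
      }
      next
    }
    j <- match(cp, table$items$item)
    if (is.na(j)) next
    cat <- table$items$category[j]
    ev_cost <- rep(table$items$event_cost[j], n)
    if (cp == "stroke") {
      fatal <- !is.na(sim$death_cause) & sim$death_cause == "stroke" &
        !is.na(on) & sim$death_cycle == on
      ev_cost[fatal] <- table$stroke_death_cost
    }
    sub_cost <- if (transient) table$edema_follow_up else table$items$subsequent_cost[j]
    # gangrene and amputation leave no ongoing ulcer-care cost of their own
    if (cp %in% c("gangrene", "amputation")) sub_cost <- table$items$subsequent_cost[j]
    out[[cat]] <- out[[cat]] + event_year * ev_cost + later_years * sub_cost
  }

  for (ev in acute_event_types) {
    cat <- if (ev %in% c("severe_hypo", "minor_hypo")) "hypoglycemia"
           else "other_acute"
    out[[cat]] <- out[[cat]] + sim$acute[[ev]] * table$acute[[ev]]
  }
  out
}

#' Per-cycle human-capital indirect costs for a simulated arm
#'
#' Disability days accrue for incident complications and acute events in
#' their cycle (capped at the working year) and are valued at the
#' sex-specific daily salary within the working-age window.
#'
#' @param sim an `arm_sim` from [simulate_arm()].
#' @param durations a [disability_durations()] vector (workdays).
#' @param salary a [salary_table()].
#' @return an `n x horizon` matrix of MXN.
#' @export
indirect_cycles <- function(sim, durations = disability_durations(),
                            salary = salary_table()) {
  n <- sim$n; TT <- sim$horizon
  days <- matrix(0, n, TT)
  comps <- colnames(sim$onset)
  for (ci in seq_along(comps)) {
    d <- durations[[comps[ci]]]
    if (is.null(d) || d == 0) next
    on <- sim$onset[, ci]
    hit <- which(!is.na(on) & on >= 1)
    for (i in hit) days[i, on[i]] <- days[i, on[i]] + d
  }
  for (ev in acute_event_types) {
    d <- durations[[ev]]
    if (is.null(d) || d == 0) next
    days <- days + sim$acute[[ev]] * d
  }
  days <- pmin(days, salary$workdays_per_year)
  age_mat <- outer(sim$baseline$age, seq_len(TT) - 1, "+")
  working <- age_mat >= salary$first_income_age & age_mat < salary$retirement_age
  daily <- ifelse(sim$baseline$sex == "male", salary$daily_salary_male,
                  salary$daily_salary_female)
  days * working * daily
}
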