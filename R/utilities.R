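# Health-state utilities and disutilities. Combination rules: when multiple
# chronic conditions are present the LOWEST per-condition utility applies
# (not additive decrements); one-off event disutilities are subtracted in
# the event cycle on top of that; the result is clamped at 0.
#
# Chronic states keep their decrement every cycle they are active (the
# published one-off/health-state column split lists chronic states such as
# hemodialysis under "one-off"; the lowest-utility rule makes them
# per-cycle here, the standard convention). Events with lasting impact
# (myocardial infarction, stroke, amputation, kidney transplant) switch the
# patient to a post-event health-state value.

#' Utility table
#'
#' Baseline utility 0.785 (type 1/2 diabetes, no complications), chronic
#' condition utilities (baseline minus the published decrement, or the
#' published post-event health-state value), and one-off event
#' disutilities. Microalbuminuria, healed ulcer and post insulin edema
#' carry no disutility. Gangrene, ketoacidosis and lactic acidosis have no
#' published utility entry and carry none (documented choice).
#'
#' @param baseline utility with no complications (default 0.785).
#' @param overrides named list replacing entries of `condition_values` or
#'   `one_off` (e.g. `list(one_off = c(major_hypo = -0.05))`).
#' @return object of class `utility_table`.
#' @export
utility_table <- function(baseline = 0.785, overrides = NULL) {
  if (baseline <= 0 || baseline > 1) abort("baseline utility must lie in (0, 1]")
  decrement <- c(
    angina = -0.09, congestive_heart_failure = -0.108,
    peripheral_vascular_disease = -0.061, gross_proteinuria = -0.048,
    hemodialysis = -0.164, peritoneal_dialysis = -0.204,
    background_retinopathy = -0.04, proliferative_retinopathy = -0.07,
    macular_edema = -0.04, severe_visual_loss = -0.074,
    neuropathy = -0.084, active_ulcer = -0.17,
    microalbuminuria = 0, healed_ulcer = 0, post_edema = 0, gangrene = 0
  )
  condition_values <- c(baseline + decrement,
                        myocardial_infarction = 0.73,
                        stroke = 0.621,
                        transplant = 0.762,
                        amputation = 0.505)
  one_off <- c(
    myocardial_infarction = -0.055, angina = -0.09,
    congestive_heart_failure = -0.108, stroke = -0.164,
    peripheral_vascular_disease = -0.061, gross_proteinuria = -0.048,
    cataract = -0.016, active_ulcer = -0.17, amputation = -0.28,
    major_hypo = -0.047, minor_hypo = -0.014
  )
  tbl <- list(baseline = baseline,
              condition_values = condition_values,
              one_off = one_off)
  tbl$condition_values[["cataract"]] <- baseline  # resolved by operation
  if (!is.null(overrides)) {
    for (grp in names(overrides)) {
      if (!grp %in% c("condition_values", "one_off", "baseline")) {
        abort(paste0("unknown utility_table group: ", grp))
      }
      if (grp == "baseline") tbl$baseline <- overrides$baseline
      else tbl[[grp]][names(overrides[[grp]])] <- overrides[[grp]]
    }
  }
  if (any(tbl$condition_values > tbl$baseline + 1e-12)) {
    abort("condition utilities cannot exceed the baseline utility")
  }
  structure(tbl, class = "utility_table")
}

#' Utility of a single chronic condition
#'
#' Post-event health-state value where one exists (post myocardial
#' infarction 0.73, post stroke 0.621, kidney transplant 0.762, post
#' amputation 0.505), otherwise baseline minus the condition's decrement
#' (e.g. neuropathy 0.785 - 0.084 = 0.701); conditions with no disutility
#' return the baseline.
#'
#' @param condition condition name from the table vocabulary.
#' @param table a [utility_table()].
#' @return utility value.
#' @export
#' @examples
#' condition_utility("myocardial_infarction") # 0.73
#' condition_utility("neuropathy")            # 0.701
#' condition_utility("microalbuminuria")      # 0.785
condition_utility <- function(condition, table = utility_table()) {
  v <- table$condition_values[condition]
  if (any(is.na(v))) {
    abort(paste0("unknown condition: ",
                 paste(condition[is.na(v)], collapse = ", ")))
  }
  unname(v)
}

#' Per-cycle utility of a patient
#'
#' Minimum of the per-condition utilities over the active chronic states
#' (the baseline 0.785 if none), minus the summed one-off disutilities of
#' this cycle's events, clamped below at 0.
#'
#' @param active_conditions character vector of active chronic states.
#' @param events character vector (or named counts) of this cycle's events
#'   carrying one-off disutilities (e.g. `"major_hypo"`, an incident
#'   `"myocardial_infarction"`).
#' @param table a [utility_table()].
#' @return utility in `[0, 1]`.
#' @export
#' @examples
#' annual_utility(character(0))                           # 0.785
#' annual_utility(c("myocardial_infarction", "stroke"))   # 0.621
#' annual_utility(character(0), "major_hypo")             # 0.738
annual_utility <- function(active_conditions = character(0),
                           events = character(0),
                           table = utility_table()) {
  u <- table$baseline
  if (length(active_conditions) > 0) {
    u <- min(u, min(condition_utility(active_conditions, table)))
  }
  if (length(events) > 0) {
    if (is.null(names(events))) {
      counts <- table(events)
      ev_names <- names(counts)
      ev_counts <- as.numeric(counts)
    } else {
      ev_names <- names(events)
      ev_counts <- as.numeric(events)
    }
    bad <- setdiff(ev_names, names(table$one_off))
    if (length(bad) > 0) {
      abort(paste0("no one-off disutility defined for: ",
                   paste(bad, collapse = ", ")))
    }
    u <- u + sum(table$one_off[ev_names] * ev_counts)
  }
  max(0, min(1, u))
}

#' QALY increment for one cycle
#'
#' @param utility utility in `[0, 1]`.
#' @param years cycle length (default 1).
#' @param discount_factor factor from [discount_factor()].
#' @return discounted QALYs accrued.
#' @export
qaly_increment <- function(utility, years = 1, discount_factor = 1) {
  if (any(utility < 0 | utility > 1)) abort("utility must lie in [0, 1]")
  utility * years * discount_factor
}

#' Per-cycle utility matrix for a simulated arm
#'
#' Vectorized application of the lowest-utility rule and the one-off event
#' disutilities to every patient-cycle; dead cycles score 0.
#'
#' @param sim an `arm_sim` from [simulate_arm()].
#' @param table a [utility_table()].
#' @return an `n x horizon` matrix of utilities in `[0, 1]`.
#' @export
# Chronic-state mapping from simulated complications:
#   - transient ulcer/gangrene states: active-ulcer decrement in the onset
#     cycle only, healed (no disutility) afterwards;
#   - amputation: one-off -0.28 at onset, post-amputation 0.505 after;
#   - MI / stroke: event one-off at onset plus post-state value from onset;
#   - cataract: one-off -0.016 at onset only (resolved by the operation);
#   - end-stage renal disease: modality-specific value;
#   - other chronic states: baseline minus decrement from onset onwards.
# Dead cycles score 0.
utility_cycles <- function(sim, table = utility_table()) {
  n <- sim$n; TT <- sim$horizon
  ly <- life_years(sim)
  alive <- outer(ly, seq_len(TT), ">=")
  u <- matrix(table$baseline, n, TT)
  comps <- colnames(sim$onset)
  tinfo <- sim$params$complications
  apply_state <- function(u, sel_mat, value) {
    # min-rule: active condition caps utility at its value
    pmin(u, ifelse(sel_mat, value, Inf))
  }
  one_off_mat <- matrix(0, n, TT)
  for (ci in seq_along(comps)) {
    cp <- comps[ci]
    on <- sim$onset[, ci]
    if (all(is.na(on))) next
    started <- !is.na(on) & outer(on, seq_len(TT), "<=")
    event_year <- !is.na(on) & outer(on, seq_len(TT), "==")
    transient <- isTRUE(tinfo$transient[match(cp, tinfo$name)])
    if (cp == "end_stage_renal_disease") {
      for (mod in c("hemodialysis", "peritoneal_dialysis", "transplant")) {
        sel <- !is.na(sim$modality) & sim$modality == mod
        u <- apply_state(u, started & sel, condition_utility(mod, table))
      }
    } else if (transient) {
      if (cp != "gangrene") {
        u <- apply_state(u, event_year,
                         condition_utility("active_ulcer", table))
      }
    } else if (cp == "cataract") {
      # one-off only; handled below
    } else {
      u <- apply_state(u, started, condition_utility(cp, table))
    }
    # event-cycle one-off applies on top of the state value only for events
    # with lasting impact or resolved procedures; purely chronic states
    # (angina, CHF, PVD, proteinuria, dialysis) carry their decrement
    # through the min rule alone
    if (cp %in% c("myocardial_infarction", "stroke", "amputation", "cataract")) {
      one_off_mat <- one_off_mat + event_year * table$one_off[[cp]]
    }
  }
  one_off_mat <- one_off_mat +
    sim$acute$severe_hypo * table$one_off[["major_hypo"]] +
    sim$acute$minor_hypo * table$one_off[["minor_hypo"]]
  u <- pmin(1, pmax(0, u + one_off_mat))
  u * alive
}
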