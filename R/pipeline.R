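# Configuration and end-to-end pipeline driver. The config is a plain YAML
# (or JSON) file; every field is optional and defaults to the packaged
# published-table values. All randomness flows from the three seeds in the
# config; MXN is the canonical currency in every stored artifact, USD
# columns are derived at report time at the fixed 18.390 rate.

#' Pipeline configuration
#'
#' @param n_patients cohort size (>= 1).
#' @param horizon simulation horizon in years, 1-70.
#' @param cohort_seed,sim_seed,psa_seed integer seeds for cohort
#'   generation, arm simulation (shared across arms: common random
#'   numbers) and the acceptability-curve draws.
#' @param discount a [discount_spec()].
#' @param include_indirect_costs logical for the main run.
#' @param cohort_spec a [default_imss_spec()]-style spec (its `n` and
#'   `seed` are replaced by `n_patients` / `cohort_seed`).
#' @param disease_params_file optional YAML path read with
#'   [read_disease_params()]; `NULL` uses the packaged synthetic defaults.
#' @param ceac_n_outer,ceac_n_inner acceptability-curve sample sizes;
#'   `ceac_n_outer = 0` skips the curve.
#' @param cost_cv coefficient of variation for cost uncertainty in the
#'   acceptability curve.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 192, horizon = 70,
                            cohort_seed = 20160101, sim_seed = 1,
                            psa_seed = 2, discount = discount_spec(),
                            include_indirect_costs = FALSE,
                            cohort_spec = default_imss_spec(),
                            disease_params_file = NULL,
                            ceac_n_outer = 0, ceac_n_inner = 100,
                            cost_cv = 0.2) {
  if (n_patients < 1) abort("config: `n_patients` must be >= 1")
  if (horizon < 1 || horizon > 70) abort("config: `horizon` must lie in [1, 70]")
  if (!inherits(discount, "discount_spec")) abort("config: `discount` must be a discount_spec")
  if (!is.null(disease_params_file) && !file.exists(disease_params_file)) {
    abort(paste0("config: disease_params_file does not exist: ",
                 disease_params_file))
  }
  structure(list(n_patients = n_patients, horizon = horizon,
                 cohort_seed = cohort_seed, sim_seed = sim_seed,
                 psa_seed = psa_seed, discount = discount,
                 include_indirect_costs = include_indirect_costs,
                 cohort_spec = cohort_spec,
                 disease_params_file = disease_params_file,
                 ceac_n_outer = ceac_n_outer, ceac_n_inner = ceac_n_inner,
                 cost_cv = cost_cv),
            class = "pipeline_config")
}

#' Load / save a pipeline configuration
#'
#' YAML by default, JSON accepted by extension. An empty file yields the
#' all-defaults configuration (published table values, synthetic disease
#' parameters). Unknown fields raise a validation error naming the field.
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  if (is.null(x)) x <- list()
  known <- c("n_patients", "horizon", "cohort_seed", "sim_seed", "psa_seed",
             "rate_costs", "rate_effects", "include_indirect_costs",
             "disease_params_file", "ceac_n_outer", "ceac_n_inner",
             "cost_cv", "cohort_spec")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    abort(paste0("config: unknown field(s): ", paste(unknown, collapse = ", ")))
  }
  disc <- discount_spec(x$rate_costs %||% 0.05, x$rate_effects %||% 0.05)
  spec <- default_imss_spec()
  if (!is.null(x$cohort_spec)) {
    x$cohort_spec$complication_prev <- unlist(x$cohort_spec$complication_prev) %||%
      spec$complication_prev
    x$cohort_spec$med_prev <- unlist(x$cohort_spec$med_prev) %||% spec$med_prev
    spec[names(x$cohort_spec)] <- x$cohort_spec
    validate_cohort_spec(spec)
  }
  pipeline_config(
    n_patients = x$n_patients %||% 192,
    horizon = x$horizon %||% 70,
    cohort_seed = x$cohort_seed %||% 20160101,
    sim_seed = x$sim_seed %||% 1,
    psa_seed = x$psa_seed %||% 2,
    discount = disc,
    include_indirect_costs = isTRUE(x$include_indirect_costs),
    cohort_spec = spec,
    disease_params_file = x$disease_params_file,
    ceac_n_outer = x$ceac_n_outer %||% 0,
    ceac_n_inner = x$ceac_n_inner %||% 100,
    cost_cv = x$cost_cv %||% 0.2
  )
}

#' @rdname load_config
#' @param config a `pipeline_config`.
#' @export
save_config <- function(config, path) {
  x <- list(
    n_patients = config$n_patients, horizon = config$horizon,
    cohort_seed = config$cohort_seed, sim_seed = config$sim_seed,
    psa_seed = config$psa_seed,
    rate_costs = config$discount$rate_costs,
    rate_effects = config$discount$rate_effects,
    include_indirect_costs = config$include_indirect_costs,
    ceac_n_outer = config$ceac_n_outer,
    ceac_n_inner = config$ceac_n_inner,
    cost_cv = config$cost_cv
  )
  if (!is.null(config$disease_params_file)) {
    x$disease_params_file <- config$disease_params_file
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full pipeline and write its artifacts
#'
#' Generates the cohort, runs the default scenario suite (base case,
#' secondary indirect-cost case, one-way sensitivity and subgroup
#' scenarios), optionally computes the acceptability curve, and writes:
#' `cohort.csv`, `base_case.json`, `base_case_costs.csv`,
#' `scenario_report.csv`, `scenario_report.md`, and (when requested)
#' `ceac.csv` and `ceac.png`. Reruns with the same config are numerically
#' identical.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for artifacts (created if missing).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the base-case `cea_result`, the scenario
#'   report tibble, the `ceac_curve` (or NULL) and the written file paths.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pumpcea] ", ...)

  params <- if (is.null(config$disease_params_file)) disease_params()
            else read_disease_params(config$disease_params_file)
  spec <- config$cohort_spec
  spec$n <- config$n_patients
  spec$seed <- config$cohort_seed

  say("generating cohort (n = ", spec$n, ", seed = ", spec$seed, ")")
  cohort <- generate_cohort(spec)
  paths <- c(cohort = file.path(output_dir, "cohort.csv"))
  write_cohort(cohort, paths[["cohort"]])

  say("running scenario suite (horizon = ", config$horizon, ")")
  suite <- default_scenario_suite(seed = config$sim_seed)
  report <- run_suite(suite, cohort, params = params, disc = config$discount,
                      horizon = config$horizon)
  base <- run_scenario(scenario_spec("base_case", seed = config$sim_seed,
                                     include_indirect_costs = config$include_indirect_costs),
                       cohort, params = params, disc = config$discount,
                       horizon = config$horizon)

  paths["base_case"] <- file.path(output_dir, "base_case.json")
  jsonlite::write_json(glance(base), paths[["base_case"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["base_case_costs"] <- file.path(output_dir, "base_case_costs.csv")
  utils::write.csv(tidy(base), paths[["base_case_costs"]], row.names = FALSE)
  paths["scenario_report"] <- file.path(output_dir, "scenario_report.csv")
  utils::write.csv(report, paths[["scenario_report"]], row.names = FALSE)
  paths["scenario_report_md"] <- file.path(output_dir, "scenario_report.md")
  writeLines(report_markdown(report), paths[["scenario_report_md"]])

  curve <- NULL
  if (config$ceac_n_outer > 0) {
    say("computing acceptability curve (", config$ceac_n_outer, " x ",
        config$ceac_n_inner, ")")
    runner <- make_psa_runner(spec = spec, params = params,
                              disc = config$discount,
                              horizon = config$horizon,
                              cost_cv = config$cost_cv)
    curve <- ceac(runner, n_outer = config$ceac_n_outer,
                  n_inner = config$ceac_n_inner, seed = config$psa_seed)
    paths["ceac"] <- file.path(output_dir, "ceac.csv")
    utils::write.csv(as.data.frame(curve), paths[["ceac"]], row.names = FALSE)
    paths["ceac_plot"] <- file.path(output_dir, "ceac.png")
    ggplot2::ggsave(paths[["ceac_plot"]], autoplot(curve),
                    width = 7, height = 5, dpi = 150)
  }
  say("done; artifacts in ", output_dir)
  invisible(list(base_case = base, report = report, ceac = curve,
                 paths = paths))
}

report_markdown <- function(report) {
  cols <- c("scenario", "icer_per_qaly", "icer_per_qaly_usd", "cost_csii",
            "qaly_csii", "cost_mdi", "qaly_mdi")
  df <- report[, cols]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, format = "f", digits = 2,
                                                 big.mark = ","))
  header <- paste0("| ", paste(cols, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c("# Scenario report", "", header, sep, rows)
}
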