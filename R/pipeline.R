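# End-to-end orchestration: simulate/read -> cohort -> screen -> onset ->
# regression, with a run manifest and deterministic TSV outputs.

#' Pipeline run configuration
#'
#' @param input_dir directory holding `demo.csv`, `drug.csv`, `reac.csv`,
#'   `hist.csv`; mutually exclusive with `simulation`.
#' @param simulation a [sim_config()]; when given, the run starts by
#'   generating synthetic tables (the run `seed` overrides the simulation
#'   seed so one seed governs the whole run).
#' @param target_pt_code target event preferred-term code.
#' @param min_drug_cases drugs-of-interest threshold (default 5).
#' @param min_tto_cases strict per-drug threshold for Weibull fitting
#'   (default 10).
#' @param quantile_type quantile rule used throughout.
#' @param haldane_correction apply the +0.5 correction in the ROR screen.
#' @param alpha_enter,alpha_remove stepwise significance levels.
#' @param excluded_candidates drugs never eligible for stepwise selection.
#' @param subset_drugs drugs for the by-sex subset models, or `NULL` to
#'   derive them from the run (stepwise-selected drugs that also pass the
#'   time-to-onset threshold; falling back to the two most frequent
#'   selected drugs).
#' @param seed integer seed governing the entire run.
#' @param output_dir optional directory for the TSV outputs and manifest.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, simulation = NULL,
                       target_pt_code = "10056979",
                       min_drug_cases = 5L, min_tto_cases = 10L,
                       quantile_type = 6L, haldane_correction = FALSE,
                       alpha_enter = 0.05, alpha_remove = 0.05,
                       excluded_candidates = c("albumin tannate",
                                               "prednisolone", "loperamide"),
                       subset_drugs = NULL,
                       seed = 1L, output_dir = NULL) {
  if (is.null(input_dir) && is.null(simulation)) {
    simulation <- sim_config(seed = seed)
  }
  if (!is.null(input_dir) && !is.null(simulation)) {
    stop("give either input_dir or simulation, not both", call. = FALSE)
  }
  stopifnot(min_drug_cases >= 1, min_tto_cases >= 1)
  structure(list(
    input_dir = input_dir, simulation = simulation,
    target_pt_code = target_pt_code,
    min_drug_cases = as.integer(min_drug_cases),
    min_tto_cases = as.integer(min_tto_cases),
    quantile_type = quantile_type,
    haldane_correction = isTRUE(haldane_correction),
    alpha_enter = alpha_enter, alpha_remove = alpha_remove,
    excluded_candidates = excluded_candidates,
    subset_drugs = subset_drugs,
    seed = as.integer(seed), output_dir = output_dir),
    class = "run_config")
}

#' Run the full signal-detection pipeline
#'
#' Executes dataset construction, the reporting-odds-ratio screen, the
#' time-to-onset Weibull profile, the stepwise-adjusted logistic model and
#' the by-sex subset models in order, logging every exclusion count. A
#' failing stage aborts with the stage name; partial TSV outputs written up
#' to that point are preserved. Identical config and seed reproduce
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return Object of class `srs_run`: list with `analysis` (the
#'   `analysis_table`), `screen`, `onset_records`, `profile`, `model`,
#'   `by_sex`, `truth` (for simulated runs), `tables` (the six report
#'   tibbles) and `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  timings <- list()
  out_dir <- config$output_dir
  tables <- list()

  flush_tables <- function() {
    if (!is.null(out_dir) && length(tables)) {
      write_report_tables(tables, out_dir)
    }
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      flush_tables()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  truth <- NULL
  data <- stage("input", {
    if (!is.null(config$simulation)) {
      sc <- config$simulation
      sc$seed <- config$seed
      sim <- simulate_srs(sc)
      truth <- sim$truth
      sim$data
    } else {
      read_jader_tables(file.path(config$input_dir, "demo.csv"),
                        file.path(config$input_dir, "drug.csv"),
                        file.path(config$input_dir, "reac.csv"),
                        file.path(config$input_dir, "hist.csv"))
    }
  })

  at <- stage("cohort", build_analysis_table(
    data, target_pt_code = config$target_pt_code,
    quantile_type = config$quantile_type))
  doi <- stage("drugs_of_interest",
               drugs_of_interest(at, config$min_drug_cases))
  outcomes <- stage("outcomes", tabulate_outcomes(at))
  screen <- stage("ror_screen", ror_screen(
    at, doi$drug, haldane = config$haldane_correction))
  onset_records <- stage("tto_table", build_tto_table(at))
  profile <- stage("tto_profile", tto_profile(
    onset_records, min_cases = config$min_tto_cases,
    quantile_type = config$quantile_type))
  model <- stage("regression", fit_signal_model(
    at, candidates = doi$drug,
    excluded_candidates = config$excluded_candidates,
    alpha_enter = config$alpha_enter, alpha_remove = config$alpha_remove))

  subset_drugs <- config$subset_drugs
  if (is.null(subset_drugs)) {
    eligible <- names(profile$fits)
    subset_drugs <- intersect(model$selected_drugs, eligible)
    if (!length(subset_drugs) && length(model$selected_drugs)) {
      cnt <- doi$n_cases[match(model$selected_drugs, doi$drug)]
      subset_drugs <- model$selected_drugs[order(-cnt)][
        seq_len(min(2L, length(model$selected_drugs)))]
    }
  }
  by_sex <- stage("subset_by_sex", subset_by_sex(at, subset_drugs))

  fc <- at$flowchart
  flow_tbl <- tibble::tibble(
    stage = c("input_reports", "excluded_missing_demographics",
              "complete_demographics", "excluded_ebmi_outliers",
              "analysis_table", "target_event_cases",
              "time_to_onset_cases", "negative_durations_dropped"),
    count = c(fc[["n_input"]], fc[["n_excluded_missing"]],
              fc[["n_complete"]], fc[["n_excluded_outlier"]],
              fc[["n_analysis"]], fc[["n_event"]],
              attr(onset_records, "n_tto") %||% 0L,
              attr(onset_records, "n_negative_dropped") %||% 0L))

  reg_all <- regression_table(model, at, population = "all")
  reg_sex <- rbind(
    regression_table(by_sex$female, at, population = "female",
                     subset_sex = "female"),
    regression_table(by_sex$male, at, population = "male",
                     subset_sex = "male"))

  tables <- list(flowchart = flow_tbl, drug_groups = doi,
                 ror_screen = screen, tto_summary = profile$table,
                 regression_all = reg_all, regression_by_sex = reg_sex,
                 outcomes = outcomes)

  manifest <- list(
    seed = config$seed,
    target_pt_code = config$target_pt_code,
    thresholds = list(min_drug_cases = config$min_drug_cases,
                      min_tto_cases = config$min_tto_cases),
    stepwise = list(alpha_enter = config$alpha_enter,
                    alpha_remove = config$alpha_remove,
                    excluded_candidates = config$excluded_candidates),
    input = if (is.null(config$input_dir)) "simulated" else config$input_dir,
    subset_drugs = subset_drugs,
    exclusions = as.list(fc),
    outputs = c("flowchart.tsv", "drug_groups.tsv", "ror_screen.tsv",
                "tto_summary.tsv", "regression_all.tsv",
                "regression_by_sex.tsv"),
    stage_seconds = timings)

  if (!is.null(out_dir)) {
    write_report_tables(tables, out_dir)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }

  structure(list(
    config = config, data = data, truth = truth, analysis = at,
    drug_groups = doi, outcomes = outcomes, screen = screen,
    onset_records = onset_records, profile = profile, model = model,
    by_sex = by_sex, tables = tables, manifest = manifest),
    class = "srs_run")
}

#' @export
print.srs_run <- function(x, ...) {
  cat("<srs_run>\n")
  fc <- x$analysis$flowchart
  cat(sprintf("  analysis table: %d cases, %d target-event cases\n",
              fc[["n_analysis"]], fc[["n_event"]]))
  cat(sprintf("  drugs of interest: %d; signal-positive: %d\n",
              nrow(x$drug_groups), sum(x$screen$signal)))
  cat(sprintf("  stepwise-selected drugs: %s\n",
              if (length(x$model$selected_drugs))
                paste(x$model$selected_drugs, collapse = ", ") else "(none)"))
  cat(sprintf("  Weibull-profiled drugs: %s\n",
              if (length(x$profile$fits))
                paste(names(x$profile$fits), collapse = ", ") else "(none)"))
  invisible(x)
}
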