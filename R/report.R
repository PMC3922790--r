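#' Write / read a cohort as delimited text
#'
#' Cohorts are stored as UTF-8 CSV with a header row, one row per child,
#' alongside a JSON column dictionary describing each column's type and
#' levels. `read_cohort` validates the schema on the way in, so a written
#' cohort round-trips value-identically.
#'
#' @param cohort Cohort data frame.
#' @param path CSV path; the dictionary is written next to it as
#'   `<path>.dict.json`.
#' @return `read_cohort` returns the validated cohort; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  dict <- lapply(names(cohort), function(cl) {
    v <- cohort[[cl]]
    list(column = cl,
         type = if (is.factor(v)) "categorical"
                else if (all(v %in% c(0, 1) | is.na(v))) "binary"
                else if (is.numeric(v)) "numeric" else "text",
         levels = if (is.factor(v)) levels(v) else NULL)
  })
  jsonlite::write_json(dict, paste0(path, ".dict.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  for (cl in intersect(names(raw), c("education", "race_eth", "region",
                                     "consistency"))) {
    lev <- switch(cl, education = EDUCATION_LEVELS, race_eth = RACE_LEVELS,
                  region = REGION_LEVELS, consistency = CONSISTENCY_LEVELS)
    raw[[cl]] <- factor(raw[[cl]], levels = lev)
  }
  validate_cohort(raw)
}

#' Round ratio estimates for display
#'
#' Publication tables round odds ratios and their limits to two significant
#' figures; machine outputs keep full precision and rounding happens only at
#' the display layer.
#'
#' @param x Numeric vector.
#' @return Numeric vector rounded to 2 significant figures.
#' @export
format_or <- function(x) signif(x, 2)

#' Combined analysis of a cohort
#'
#' Runs the full misclassification-naive battery (crude, matching-factors
#' only, fully adjusted, consistency-stratified frequentist models and the
#' naive Bayesian model) and, when scenarios are supplied, the corrected
#' joint model per scenario, returning one stacked results table. An empty
#' scenario list yields the naive rows only, with a warning. Convergence
#' failures in corrected rows are flagged, not fatal.
#'
#' @param cohort Cohort data frame (validated on entry).
#' @param scenarios A `scenario_grid` / list of scenarios, possibly empty.
#' @param priors Optional [prior_set()] for the Bayesian outcome models.
#' @param config An [mcmc_config()].
#' @return A list: `table` (rows: the naive models, then one corrected row
#'   per scenario), `windows` (forest-plot-ready per-window estimates) and
#'   `grid` (the raw [run_grid()] result or `NULL`).
#' @export
analyze_cohort <- function(cohort, scenarios = list(), priors = NULL,
                           config = mcmc_config()) {
  cohort <- validate_cohort(cohort)
  naive_freq <- fit_naive_models(cohort)
  strata <- fit_consistency_strata(cohort)
  dsn <- build_design(cohort, "reported_prenatal", charge_covariates())
  nb <- fit_bayes_logistic(dsn, priors = priors, config = config,
                           on_nonconvergence = "warn")
  tab <- rbind(naive_freq, strata, nb$estimate)
  grid_res <- NULL
  if (length(scenarios)) {
    spec <- joint_model_spec(scenario = scenarios[[1]],
                             outcome_priors = priors)
    grid_res <- run_grid(cohort, scenarios, spec_template = spec,
                         config = config)
    corrected <- data.frame(
      model_label = paste0("corrected: ", grid_res$label),
      or_point = grid_res$or_point, ci_lower = grid_res$ci_lower,
      ci_upper = grid_res$ci_upper, limit_ratio = grid_res$limit_ratio,
      interval_kind = "credible", estimable = grid_res$converged,
      note = grid_res$note, stringsAsFactors = FALSE
    )
    tab <- rbind(as.data.frame(tab), corrected)
  } else {
    warning("no misclassification scenarios supplied; ",
            "reporting naive models only")
  }
  list(table = as.data.frame(tab),
       windows = fit_window_models(cohort),
       grid = grid_res)
}

#' Display-rounded results table
#'
#' @param table A results table from [analyze_cohort()].
#' @return The table with OR, limits and limit ratio rounded to two
#'   significant figures.
#' @export
display_table <- function(table) {
  for (cl in intersect(names(table),
                       c("or_point", "ci_lower", "ci_upper", "limit_ratio"))) {
    table[[cl]] <- format_or(table[[cl]])
  }
  table
}

#' Forest-plot-ready scenario grid output
#'
#' @param grid_result A [run_grid()] result.
#' @return Data frame with columns `x` (scenario label), `group`, `y`
#'   (posterior OR), `ymin`, `ymax` (credible limits).
#' @export
grid_plot_data <- function(grid_result) {
  data.frame(x = grid_result$label, group = grid_result$group,
             y = grid_result$or_point, ymin = grid_result$ci_lower,
             ymax = grid_result$ci_upper, stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' Records, as JSON, everything needed to regenerate a run's outputs
#' byte-identically: the seeds, the configuration, every output file path,
#' wall time and any convergence summaries. Written even when a stage fails
#' part-way (call it from `on.exit()` in driver scripts).
#'
#' @param path Output JSON path.
#' @param seeds Named list/vector of seeds used.
#' @param config Any serializable configuration object.
#' @param outputs Character vector of output file paths.
#' @param convergence Optional convergence summary data frame.
#' @param status `"complete"` or `"partial"`.
#' @param started `proc.time()` snapshot from the start of the run.
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(path, seeds, config = NULL, outputs = character(0),
                         convergence = NULL, status = "complete",
                         started = NULL) {
  manifest <- list(
    package = "bayesmisclass",
    version = as.character(utils::packageVersion("bayesmisclass")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    status = status,
    seeds = as.list(seeds),
    config = config,
    outputs = as.list(outputs),
    wall_time_s = if (!is.null(started)) {
      unname((proc.time() - started)["elapsed"])
    } else NULL,
    convergence = convergence
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(manifest)
}
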