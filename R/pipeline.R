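#' End-to-end pipeline configuration
#'
#' Bundles the generator settings, sensor set, model list and evaluation
#' options of one run. Defaults reproduce the reference training protocol;
#' `max_epochs` and `patience` are exposed because desk-scale synthetic runs
#' need far fewer epochs than the full protocol's 500.
#'
#' @param generator A [generator_config()].
#' @param sensors `"dual"`, `"pelvis"` or `"foot"`.
#' @param models Character vector of model types to evaluate.
#' @param structures Structures to evaluate.
#' @param k_folds Number of cross-validation folds.
#' @param fold_seed Seed for the fold plan.
#' @param model_seed Seed for model initialization and training.
#' @param max_epochs,patience Training-schedule overrides applied to every
#'   network spec.
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes the step table, fold metrics, summary and a manifest there.
#' @return Object of class `runload_run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       sensors = "dual",
                       models = c("ts_lstm", "mean"),
                       structures = runload_structures(),
                       k_folds = 5L,
                       fold_seed = 1L,
                       model_seed = 1L,
                       max_epochs = 500L,
                       patience = 30L,
                       out_dir = NULL) {
  stopifnot(inherits(generator, "runload_config"))
  sensors <- match.arg(sensors, c("dual", "pelvis", "foot"))
  bad <- setdiff(models, .model_types)
  if (length(bad)) stop("unknown model type(s): ", paste(bad, collapse = ", "))
  structures <- match.arg(structures, .structures, several.ok = TRUE)
  structure(list(generator = generator, sensors = sensors, models = models,
                 structures = structures, k_folds = as.integer(k_folds),
                 fold_seed = as.integer(fold_seed),
                 model_seed = as.integer(model_seed),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), out_dir = out_dir),
            class = "runload_run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; the `generator`
#' key holds [generator_config()] arguments. Unknown keys are an error, so
#' typos fail before any compute.
#'
#' @param path YAML file path.
#' @return A `runload_run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  raw <- yaml::read_yaml(path)
  gen_args <- raw$generator
  if (!is.null(gen_args)) {
    bad <- setdiff(names(gen_args), names(formals(generator_config)))
    if (length(bad)) stop("unknown generator config key(s): ",
                          paste(bad, collapse = ", "))
  }
  run_args <- raw[setdiff(names(raw), "generator")]
  bad <- setdiff(names(run_args), names(formals(run_config)))
  if (length(bad)) stop("unknown run config key(s): ",
                        paste(bad, collapse = ", "))
  run_args$generator <- do.call(generator_config, as.list(gen_args))
  do.call(run_config, run_args)
}

#' Run the full estimation pipeline
#'
#' Chains every stage: synthetic-cohort generation (with artifact
#' injection), gait-event detection and step assembly, feature extraction,
#' subject-level cross-validated model training and evaluation. When the
#' config names an output directory, the per-step audit table, fold metrics,
#' macro-averaged summary and a manifest (seeds, settings, stage counts) are
#' written there as delimited text / JSON.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-generated `runload_cohort` (skips generation).
#' @return A `runload_report` with the additional elements `steps` and
#'   `cohort` attached as attributes-free list members.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stage <- "synth"
  result <- tryCatch({
    if (is.null(cohort)) cohort <- generate_cohort(config$generator)
    stage <- "steps"
    steps <- collect_step_data(cohort, config$sensors)
    stage <- "folds"
    folds <- make_folds(unique(steps$meta$subject_id), config$k_folds,
                        config$fold_seed)
    stage <- "models"
    specs <- lapply(config$models, function(m)
      model_spec(m, sensors = config$sensors, seed = config$model_seed,
                 max_epochs = config$max_epochs, patience = config$patience))
    report <- evaluate_models(steps, specs, folds, config$structures)
    report$steps <- steps
    report$folds <- folds
    report
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(result$steps$table, file.path(d, "steps.csv"))
    data.table::fwrite(result$fold_metrics, file.path(d, "fold_metrics.csv"))
    data.table::fwrite(result$summary, file.path(d, "summary.csv"))
    jsonlite::write_json(list(
      generator = unclass(config$generator),
      sensors = config$sensors, models = config$models,
      structures = config$structures, k_folds = config$k_folds,
      fold_seed = config$fold_seed, model_seed = config$model_seed,
      n_accepted_steps = nrow(result$steps$F),
      n_subjects = length(unique(result$steps$meta$subject_id))),
      file.path(d, "manifest.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  result
}

#' Export detected gait events of a cohort as a table
#'
#' @param cohort A `runload_cohort`.
#' @param path Optional CSV output path.
#' @return Data frame: subject_id, trial_id, ic_index, to_index, ic_time_s,
#'   to_time_s (indices at the IMU rate).
#' @export
export_events <- function(cohort, path = NULL) {
  rows <- lapply(names(cohort$trials), function(id) {
    tr <- cohort$trials[[id]]
    filt <- filter_acceleration(tr$foot$acc, tr$imu_rate)
    ev <- detect_gait_events(filt[, 3] / 9.81, tr$imu_rate)
    if (!nrow(ev)) return(NULL)
    data.frame(subject_id = tr$subject_id, trial_id = id,
               ic_index = ev$ic, to_index = ev$to,
               ic_time_s = (ev$ic - 1) / tr$imu_rate,
               to_time_s = (ev$to - 1) / tr$imu_rate)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) data.table::fwrite(out, path)
  out
}
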