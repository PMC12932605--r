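# Columnar on-disk cohort layout:
#   <path>/subjects.csv                   subject table
#   <path>/manifest.json                  rates, speeds, seed, lags, trial list
#   <path>/trials/<id>/pelvis_acc.csv     T x 3 (ap, ml, v), m/s^2
#   <path>/trials/<id>/pelvis_quat.csv    T x 4 (w, x, y, z), unit rows
#   <path>/trials/<id>/foot_acc.csv, foot_quat.csv
#   <path>/trials/<id>/vgrf.csv           T x 1, N
#   <path>/trials/<id>/ssl.csv            T x 4 (achilles, patellar, ankle, knee), N
#   <path>/trials/<id>/steps.csv          per-step truth metadata
# Doubles are serialized with %.17g so the round trip is bit-identical.

.write_num_csv <- function(x, path) {
  df <- as.data.frame(x)
  out <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  data.table::fwrite(out, path, quote = FALSE)
}

.read_num_csv <- function(path, numeric_cols = TRUE) {
  if (!file.exists(path)) stop("missing dataset file: ", path)
  dt <- data.table::fread(path, data.table = FALSE)
  dt
}

.validate_subjects <- function(subjects) {
  req <- c("subject_id", "mass_kg", "sex", "age_yr", "height_cm",
           "shoe_length_cm", "sole_thickness_cm")
  miss <- setdiff(req, names(subjects))
  if (length(miss)) stop("subject table missing columns: ",
                         paste(miss, collapse = ", "))
  num <- subjects[c("mass_kg", "age_yr", "height_cm", "shoe_length_cm",
                    "sole_thickness_cm")]
  if (any(!is.finite(as.matrix(num)))) stop("subject table has non-finite values")
  if (any(subjects$mass_kg <= 0)) stop("subject table: mass must be positive")
  if (any(subjects$height_cm <= 0)) stop("subject table: height must be positive")
  invisible(subjects)
}

#' Write a cohort to a columnar on-disk dataset
#'
#' @param cohort A `runload_cohort`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create dataset directory: ", path)
  .write_num_csv(cohort$subjects, file.path(path, "subjects.csv"))
  trial_ids <- names(cohort$trials)
  for (id in trial_ids) {
    tr <- cohort$trials[[id]]
    d <- file.path(path, "trials", id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    .write_num_csv(tr$pelvis$acc, file.path(d, "pelvis_acc.csv"))
    .write_num_csv(tr$pelvis$quat, file.path(d, "pelvis_quat.csv"))
    .write_num_csv(tr$foot$acc, file.path(d, "foot_acc.csv"))
    .write_num_csv(tr$foot$quat, file.path(d, "foot_quat.csv"))
    .write_num_csv(data.frame(vgrf = tr$vgrf), file.path(d, "vgrf.csv"))
    .write_num_csv(tr$ssl, file.path(d, "ssl.csv"))
    .write_num_csv(tr$steps, file.path(d, "steps.csv"))
  }
  manifest <- list(
    format_version = 1L,
    config = unclass(cohort$config),
    trials = lapply(trial_ids, function(id) {
      tr <- cohort$trials[[id]]
      list(id = id, subject_id = tr$subject_id, speed = tr$speed,
           imu_rate = tr$imu_rate, grf_rate = tr$grf_rate,
           body_weight_n = tr$body_weight_n, lag_s = tr$lag_s)
    })
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a cohort dataset from disk
#'
#' Validates the manifest, the subject-table invariants and quaternion unit
#' norms; errors name the offending file.
#'
#' @param path Dataset directory written by [write_dataset()].
#' @return A `runload_cohort`.
#' @export
read_dataset <- function(path) {
  man_path <- file.path(path, "manifest.json")
  if (!file.exists(man_path)) stop("missing dataset file: ", man_path)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  subjects <- .read_num_csv(file.path(path, "subjects.csv"))
  .validate_subjects(subjects)
  cfg <- manifest$config
  config <- generator_config(
    n_subjects = cfg$n_subjects, speeds = unlist(cfg$speeds),
    trial_duration = cfg$trial_duration,
    steps_per_trial = if (is.null(cfg$steps_per_trial)) NULL else cfg$steps_per_trial,
    imu_rate = cfg$imu_rate, grf_rate = cfg$grf_rate,
    noise_scale = cfg$noise_scale, corrupt_fraction = cfg$corrupt_fraction,
    coupling = cfg$coupling, sex_ratio = cfg$sex_ratio, seed = cfg$seed)
  trials <- list()
  for (entry in manifest$trials) {
    d <- file.path(path, "trials", entry$id)
    read_mat <- function(f) as.matrix(.read_num_csv(file.path(d, f)))
    foot_quat <- read_mat("foot_quat.csv")
    pelvis_quat <- read_mat("pelvis_quat.csv")
    for (nmq in list(list(q = foot_quat, f = "foot_quat.csv"),
                     list(q = pelvis_quat, f = "pelvis_quat.csv"))) {
      norms <- sqrt(rowSums(nmq$q^2))
      if (any(abs(norms - 1) > 1e-6))
        stop("non-unit quaternion rows in ", file.path(d, nmq$f))
    }
    trials[[entry$id]] <- structure(list(
      subject_id = entry$subject_id, speed = entry$speed,
      imu_rate = entry$imu_rate, grf_rate = entry$grf_rate,
      body_weight_n = entry$body_weight_n,
      pelvis = list(acc = read_mat("pelvis_acc.csv"), quat = pelvis_quat),
      foot = list(acc = read_mat("foot_acc.csv"), quat = foot_quat),
      vgrf = .read_num_csv(file.path(d, "vgrf.csv"))$vgrf,
      ssl = read_mat("ssl.csv"),
      steps = .read_num_csv(file.path(d, "steps.csv")),
      lag_s = entry$lag_s
    ), class = "runload_trial")
  }
  structure(list(subjects = subjects, trials = trials, config = config),
            class = "runload_cohort")
}
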