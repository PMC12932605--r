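#' Segment, match, filter and assemble the accepted steps of one trial
#'
#' Runs the per-trial processing chain: zero-phase 40 Hz filtering of both
#' IMUs, gait-event detection on the foot vertical acceleration, 50 N vGRF
#' stance segmentation, greedy IC matching between the two event sets,
#' 20 Hz filtering and body-weight normalization of the four load signals,
#' step exclusion rules, and time normalization of all stance-phase signals
#' to 100 samples. Step duration is half the interval between consecutive
#' right-foot GRF ICs (left/right symmetry assumption). The last GRF stance
#' of a trial has no following IC and is dropped as incomplete.
#'
#' @param trial A `runload_trial`.
#' @param profile The matching one-row subject data frame.
#' @param sensors `"dual"`, `"pelvis"` or `"foot"` (controls the assembled
#'   IMU matrix and feature battery).
#' @param exclusions An [exclusion_config()].
#' @param match_tolerance_s IC matching tolerance in seconds.
#' @param compute_features Assemble the tabular features of accepted steps.
#' @return List with `steps` (list of accepted step records), and `table`
#'   (one row per complete GRF step: durations, acceptance flag, exclusion
#'   reason, grf IC index, characteristics of accepted steps).
#' @export
make_step_samples <- function(trial, profile, sensors = "dual",
                              exclusions = exclusion_config(),
                              match_tolerance_s = 0.05,
                              compute_features = TRUE) {
  fs_i <- trial$imu_rate
  fs_g <- trial$grf_rate

  foot_filt <- filter_acceleration(trial$foot$acc, fs_i)
  pelvis_filt <- filter_acceleration(trial$pelvis$acc, fs_i)
  events <- detect_gait_events(foot_filt[, 3] / 9.81, fs_i)
  omega_foot <- angular_velocity(trial$foot$quat, 1 / fs_i)$omega
  omega_pelvis <- angular_velocity(trial$pelvis$quat, 1 / fs_i)$omega

  grf_steps <- segment_steps_grf(trial$vgrf, fs_g)
  acc_ic_times <- (events$ic - 1) / fs_i + trial$lag_s
  grf_ic_times <- (grf_steps$ic - 1) / fs_g
  matches <- match_steps(grf_ic_times, acc_ic_times, match_tolerance_s)

  ssl_bw <- apply(trial$ssl, 2, filter_and_normalize_ssl, rate = fs_g,
                  body_weight = trial$body_weight_n)

  n_grf <- nrow(grf_steps)
  steps <- list()
  rows <- list()
  if (n_grf < 2) return(list(steps = steps, table = NULL))
  for (s in seq_len(n_grf - 1L)) {            # last stance: no next IC
    ic <- grf_steps$ic[s]; to <- grf_steps$to[s]
    stance_dur <- (to - ic) / fs_g
    step_dur <- (grf_steps$ic[s + 1L] - ic) / (2 * fs_g)
    row <- data.frame(subject_id = trial$subject_id, speed = trial$speed,
                      grf_step = s, ic_grf = ic, to_grf = to,
                      ic_time_s = (ic - 1) / fs_g,
                      stance_duration = stance_dur, step_duration = step_dur,
                      accepted = FALSE, reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (!is.na(matches$reason[s])) {
      row$reason <- matches$reason[s]
      rows[[s]] <- row
      next
    }
    # stance window at IMU rate (half-open)
    ic_i <- round((ic - 1) / fs_g * fs_i) + 1L
    to_i <- round((to - 1) / fs_g * fs_i) + 1L
    to_i <- min(to_i, nrow(trial$foot$acc), nrow(omega_foot) + 1L)
    seg <- ic_i:(to_i - 1L)
    raw_acc <- cbind(trial$pelvis$acc[seg, , drop = FALSE],
                     trial$foot$acc[seg, , drop = FALSE])
    curves <- ssl_bw[ic:(to - 1L), , drop = FALSE]
    verdict <- apply_exclusions(stance_dur, step_dur, raw_acc, curves,
                                exclusions)
    row$accepted <- verdict$accepted
    row$reason <- verdict$reason
    if (verdict$accepted) {
      acc_segments <- list(
        pelvis_acc_ap = pelvis_filt[seg, 1], pelvis_acc_ml = pelvis_filt[seg, 2],
        pelvis_acc_v = pelvis_filt[seg, 3],
        foot_acc_ap = foot_filt[seg, 1], foot_acc_ml = foot_filt[seg, 2],
        foot_acc_v = foot_filt[seg, 3])
      gyr_segments <- list(
        pelvis_gyr_x = omega_pelvis[seg, 1], pelvis_gyr_y = omega_pelvis[seg, 2],
        pelvis_gyr_z = omega_pelvis[seg, 3],
        foot_gyr_x = omega_foot[seg, 1], foot_gyr_y = omega_foot[seg, 2],
        foot_gyr_z = omega_foot[seg, 3])
      ch <- .channel_names(sensors)
      all_seg <- c(acc_segments, gyr_segments)
      imu_matrix <- vapply(ch, function(nm) time_normalize(all_seg[[nm]]),
                           numeric(100))
      ssl_norm <- apply(curves, 2, time_normalize)
      colnames(ssl_norm) <- .structures
      step_rec <- list(subject_id = trial$subject_id, speed = trial$speed,
                       grf_step = s, ic_grf = ic,
                       stance_duration = stance_dur, step_duration = step_dur,
                       imu_matrix = imu_matrix, ssl_curves = ssl_norm,
                       acc_segments = acc_segments, gyr_segments = gyr_segments)
      if (compute_features) {
        fa <- assemble_features(step_rec, profile, sensors, fs_i)
        step_rec$features <- fa$features
        step_rec$flagged <- fa$flagged
      }
      for (st in .structures) {
        chars <- ssl_characteristics(ssl_norm[, st], stance_dur, st)
        row[[paste0("peak_", st)]] <- chars["peak"]
        row[[paste0("impulse_", st)]] <- chars["impulse"]
        row[[paste0("loading_rate_", st)]] <- chars["loading_rate"]
      }
      steps[[length(steps) + 1L]] <- step_rec
    }
    rows[[s]] <- row
  }
  table <- data.table::rbindlist(rows, fill = TRUE)
  list(steps = steps, table = as.data.frame(table))
}

#' Collect model-ready step data for a whole cohort
#'
#' Applies [make_step_samples()] to every trial and stacks the accepted
#' steps into model inputs: the time-normalized IMU tensor, the tabular
#' feature matrix and the target load curves per structure.
#'
#' @param cohort A `runload_cohort`.
#' @param sensors `"dual"`, `"pelvis"` or `"foot"`.
#' @param exclusions An [exclusion_config()].
#' @return Object of class `runload_steps`: list with `X` (n x channels x
#'   100 array), `F` (n x features matrix), `Y` (named list of n x 100
#'   target matrices in BW, one per structure), `meta` (data frame with
#'   subject, speed, durations), `table` (the full per-step audit table)
#'   and `sensors`.
#' @export
collect_step_data <- function(cohort, sensors = "dual",
                              exclusions = exclusion_config()) {
  all_steps <- list()
  tables <- list()
  for (id in names(cohort$trials)) {
    tr <- cohort$trials[[id]]
    profile <- cohort$subjects[cohort$subjects$subject_id == tr$subject_id, ]
    res <- make_step_samples(tr, profile, sensors, exclusions)
    if (!is.null(res$table)) {
      res$table$trial_id <- id
      tables[[id]] <- res$table
    }
    all_steps <- c(all_steps, res$steps)
  }
  n <- length(all_steps)
  if (n == 0) stop("no accepted steps in cohort")
  ch <- .channel_names(sensors)
  X <- array(0, dim = c(n, length(ch), 100L),
             dimnames = list(NULL, ch, NULL))
  Fm <- matrix(0, n, length(feature_names(sensors)),
               dimnames = list(NULL, feature_names(sensors)))
  Y <- lapply(.structures, function(s) matrix(0, n, 100L))
  names(Y) <- .structures
  meta <- data.frame(subject_id = character(n), speed = numeric(n),
                     stance_duration = numeric(n), step_duration = numeric(n),
                     ic_grf = integer(n), trial_step = integer(n),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    st <- all_steps[[i]]
    X[i, , ] <- t(st$imu_matrix[, ch, drop = FALSE])
    Fm[i, ] <- st$features
    for (s in .structures) Y[[s]][i, ] <- st$ssl_curves[, s]
    meta$subject_id[i] <- st$subject_id
    meta$speed[i] <- st$speed
    meta$stance_duration[i] <- st$stance_duration
    meta$step_duration[i] <- st$step_duration
    meta$ic_grf[i] <- st$ic_grf
    meta$trial_step[i] <- st$grf_step
  }
  structure(list(X = X, F = Fm, Y = Y, meta = meta,
                 table = as.data.frame(data.table::rbindlist(tables, fill = TRUE)),
                 sensors = sensors),
            class = "runload_steps")
}

#' @export
print.runload_steps <- function(x, ...) {
  cat(sprintf("runload steps (%s sensors): %d accepted steps, %d subjects, %d channels x 100, %d tabular features\n",
              x$sensors, nrow(x$F), length(unique(x$meta$subject_id)),
              dim(x$X)[2], ncol(x$F)))
  invisible(x)
}
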