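# Channel order used throughout: pelvis acc (ap, ml, v), pelvis gyro (x, y, z),
# foot acc (ap, ml, v), foot gyro (x, y, z). Single-sensor variants keep the
# respective 6-channel block in the same internal order.

#' IMU channel names in assembly order
#'
#' @param sensors `"dual"`, `"pelvis"` or `"foot"`.
#' @return Character vector of channel names (12 dual, 6 single): per sensor
#'   the three acceleration axes then the three angular-velocity axes.
#' @export
channel_names <- function(sensors = c("dual", "pelvis", "foot")) .channel_names(sensors)

.channel_names <- function(sensors = c("dual", "pelvis", "foot")) {
  sensors <- match.arg(sensors)
  pel <- c("pelvis_acc_ap", "pelvis_acc_ml", "pelvis_acc_v",
           "pelvis_gyr_x", "pelvis_gyr_y", "pelvis_gyr_z")
  foo <- c("foot_acc_ap", "foot_acc_ml", "foot_acc_v",
           "foot_gyr_x", "foot_gyr_y", "foot_gyr_z")
  switch(sensors, dual = c(pel, foo), pelvis = pel, foot = foo)
}

#' Subject-specific feature vector
#'
#' Ordered as mass (kg), sex (male = 1, female = 0), age (yr), height (cm),
#' shoe length (cm), sole thickness (cm).
#'
#' @param profile One-row subject data frame (see [generate_subject()]).
#' @return Named numeric vector of length 6.
#' @export
subject_features <- function(profile) {
  c(mass = profile$mass_kg,
    sex = as.numeric(profile$sex == "male"),
    age = profile$age_yr,
    height = profile$height_cm,
    shoe_length = profile$shoe_length_cm,
    sole_thickness = profile$sole_thickness_cm)
}

#' Acceleration impulse over the stance phase
#'
#' Rectangular time integral of one acceleration channel: sum of samples
#' divided by the sampling rate.
#'
#' @param acc_channel Stance-segment samples in m/s².
#' @param rate Sampling rate in Hz.
#' @return Impulse in m/s.
#' @export
acceleration_impulse <- function(acc_channel, rate) {
  stopifnot(length(acc_channel) > 0, rate > 0)
  sum(acc_channel) / rate
}

#' Sample entropy of a signal segment
#'
#' Richman–Moorman SampEn with embedding dimension `m = 2` and tolerance
#' `r = 0.2 * sd(x)` (the de facto standard parameterization):
#' `-log(A / B)` where `B` and `A` count template pairs (Chebyshev distance
#' <= r, self-matches excluded) at lengths `m` and `m + 1`. Vectorized over
#' the pairwise distance matrix; agrees with [pracma::sample_entropy()],
#' which serves as the independent cross-check in the test suite. Zero
#' variance and match-free segments return NA.
#'
#' @param x Numeric vector, length >= 10.
#' @param edim Embedding dimension (default 2).
#' @param r Tolerance; defaults to `0.2 * sd(x)`.
#' @return Sample entropy, or NA when undefined.
#' @export
sample_entropy_stat <- function(x, edim = 2L, r = 0.2 * sd(x)) {
  n <- length(x)
  if (n < 10) stop("segment too short for sample entropy")
  if (!is.finite(r) || r <= 0) return(NA_real_)
  m <- as.integer(edim)
  nt <- n - m               # number of templates at both lengths
  if (nt < 2) return(NA_real_)
  # Chebyshev distance between embeddings built incrementally per coordinate
  d_m <- abs(outer(x[1:nt], x[1:nt], "-"))
  for (k in seq_len(m - 1)) {
    idx <- (1:nt) + k
    d_m <- pmax(d_m, abs(outer(x[idx], x[idx], "-")))
  }
  d_m1 <- pmax(d_m, abs(outer(x[(1:nt) + m], x[(1:nt) + m], "-")))
  b <- (sum(d_m <= r) - nt) / 2
  a <- (sum(d_m1 <= r) - nt) / 2
  if (b == 0 || a == 0) return(NA_real_)
  -log(a / b)
}

#' Per-channel stance-segment statistics
#'
#' Acceleration channels yield impulse, maximum, mean, root mean square,
#' sample entropy (m = 2, r = 0.2 sd) and skewness (Fisher g1, bias
#' uncorrected); angular-velocity channels yield maximum and mean of the
#' signed signal. Degenerate segments (zero variance) return 0 for skewness
#' and NA for sample entropy, with `flagged = TRUE`.
#'
#' @param x Stance-segment samples at native rate.
#' @param kind `"acceleration"` or `"angular_velocity"`.
#' @param rate Sampling rate in Hz (needed for the acceleration impulse).
#' @return List with `values` (named numeric) and `flagged`.
#' @export
channel_statistics <- function(x, kind = c("acceleration", "angular_velocity"),
                               rate = 240) {
  kind <- match.arg(kind)
  if (kind == "angular_velocity")
    return(list(values = c(max = max(x), mean = mean(x)), flagged = FALSE))
  s <- sd(x)
  flagged <- FALSE
  if (s == 0) {
    sampen <- NA_real_
    skew <- 0
    flagged <- TRUE
  } else {
    sampen <- sample_entropy_stat(x)
    if (is.na(sampen)) flagged <- TRUE
    skew <- e1071::skewness(x, type = 1)
  }
  list(values = c(impulse = acceleration_impulse(x, rate),
                  max = max(x), mean = mean(x),
                  rms = sqrt(mean(x^2)),
                  sample_entropy = sampen, skewness = skew),
       flagged = flagged)
}

#' Names of the tabular features, in assembly order
#'
#' @param sensors `"dual"`, `"pelvis"` or `"foot"`.
#' @return Character vector: 6 subject features, stance and step duration,
#'   then 6 statistics per acceleration channel and 2 per angular-velocity
#'   channel (total 56 dual, 32 single).
#' @export
feature_names <- function(sensors = c("dual", "pelvis", "foot")) {
  sensors <- match.arg(sensors)
  ch <- .channel_names(sensors)
  acc <- ch[grepl("_acc_", ch)]
  gyr <- ch[grepl("_gyr_", ch)]
  c("mass", "sex", "age", "height", "shoe_length", "sole_thickness",
    "stance_duration", "step_duration",
    as.vector(t(outer(acc, c("impulse", "max", "mean", "rms",
                             "sample_entropy", "skewness"), paste, sep = "_"))),
    as.vector(t(outer(gyr, c("max", "mean"), paste, sep = "_"))))
}

#' Assemble the tabular feature vector for one step
#'
#' Six subject-specific features followed by the biomechanical block: stance
#' and step duration, six statistics per acceleration channel and two per
#' angular-velocity channel — 50 biomechanical features for the dual-IMU
#' setting, 26 for a single sensor (56 and 32 in total).
#'
#' @param step A step record as produced by [make_step_samples()]: a list
#'   with `stance_duration`, `step_duration`, and stance segments
#'   `acc_segments` / `gyr_segments` (named lists of native-rate vectors).
#' @param profile One-row subject data frame.
#' @param sensors `"dual"`, `"pelvis"` or `"foot"`.
#' @param rate IMU sampling rate in Hz.
#' @return List with `features` (named numeric vector), `flagged`.
#' @export
assemble_features <- function(step, profile, sensors = c("dual", "pelvis", "foot"),
                              rate = 240) {
  sensors <- match.arg(sensors)
  ch <- .channel_names(sensors)
  acc_ch <- ch[grepl("_acc_", ch)]
  gyr_ch <- ch[grepl("_gyr_", ch)]
  if (!all(acc_ch %in% names(step$acc_segments)) ||
      !all(gyr_ch %in% names(step$gyr_segments)))
    stop("step is missing channels required for sensors = ", sensors)
  flagged <- FALSE
  acc_stats <- unlist(lapply(acc_ch, function(nm) {
    cs <- channel_statistics(step$acc_segments[[nm]], "acceleration", rate)
    flagged <<- flagged || cs$flagged
    cs$values
  }))
  gyr_stats <- unlist(lapply(gyr_ch, function(nm)
    channel_statistics(step$gyr_segments[[nm]], "angular_velocity")$values))
  vals <- c(subject_features(profile),
            stance_duration = step$stance_duration,
            step_duration = step$step_duration,
            acc_stats, gyr_stats)
  names(vals) <- feature_names(sensors)
  # sample entropy can be undefined on degenerate segments; keep the vector
  # complete with a documented 0 sentinel and surface the flag
  nas <- is.na(vals)
  if (any(nas)) vals[nas] <- 0
  list(features = vals, flagged = flagged || any(nas))
}
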