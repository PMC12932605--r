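#' @useDynLib runload, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rnorm runif rbinom predict sd cor
#' @importFrom utils head tail
NULL

.structures <- c("achilles", "patellar", "ankle", "knee")

#' Musculoskeletal structures handled by the package
#'
#' @return Character vector of the four structure names: Achilles tendon,
#'   patellar tendon, ankle joint contact and knee joint contact force.
#' @export
runload_structures <- function() .structures

# Cohort anthropometrics (mean, sd) per sex: mass kg, age yr, height cm,
# shoe length cm, sole thickness cm.
.anthro <- list(
  male   = list(mass = c(79.8, 9.5), age = c(24.4, 6.7), height = c(186.3, 7.4),
                shoe_length = c(31.0, 1.2), sole_thickness = c(3.3, 0.8)),
  female = list(mass = c(63.2, 2.9), age = c(22.6, 3.5), height = c(173.1, 5.9),
                shoe_length = c(28.4, 1.0), sole_thickness = c(3.1, 1.2))
)

# Structure-specific load template parameters. `base` is the peak in body
# weights (BW) at 2.78 m/s for a 75 kg runner; `speed_slope` is the relative
# change per m/s; `mass_exp` a weak allometric exponent on mass; `tau_peak`
# the stance fraction at which the load peaks.
.struct_params <- data.frame(
  structure   = .structures,
  base        = c(6.5, 5.0, 10.5, 8.0),
  speed_slope = c(0.18, 0.15, 0.16, 0.14),
  mass_exp    = c(0.05, 0.05, 0.05, 0.05),
  tau_peak    = c(0.52, 0.40, 0.54, 0.45),
  tau_speed   = c(-0.01, -0.01, -0.01, -0.01),
  stringsAsFactors = FALSE
)

#' Structure-specific load template parameters
#'
#' @return Data frame with one row per structure giving the peak amplitude
#'   model (base peak in BW, relative speed slope per m/s, mass exponent) and
#'   the time-to-peak stance fraction of the raised-cosine template.
#' @export
structure_parameters <- function() .struct_params

#' Raised-cosine stance load template
#'
#' Unimodal, smooth stance-phase load profile: zero at initial contact and
#' toe-off, peaking at `tau_peak` with amplitude `peak`. Piecewise raised
#' cosine so the time integral has the closed form `peak / 2` (in units of
#' stance duration), which serves as an analytic oracle for impulse.
#'
#' @param tau Stance-phase fraction(s) in \[0, 1\].
#' @param peak Peak amplitude (any unit; typically BW).
#' @param tau_peak Stance fraction of the peak, in (0, 1).
#' @return Numeric vector of template values, same length as `tau`.
#' @export
ssl_template <- function(tau, peak, tau_peak) {
  stopifnot(tau_peak > 0, tau_peak < 1)
  out <- numeric(length(tau))
  rise <- tau >= 0 & tau <= tau_peak
  fall <- tau > tau_peak & tau <= 1
  out[rise] <- peak / 2 * (1 - cos(pi * tau[rise] / tau_peak))
  out[fall] <- peak / 2 * (1 - cos(pi * (1 - tau[fall]) / (1 - tau_peak)))
  out
}

#' Closed-form impulse of the raised-cosine template
#'
#' @param peak Template peak (BW).
#' @param stance_duration Stance duration (s).
#' @return Impulse in BW·s: `peak / 2 * stance_duration`, independent of the
#'   time-to-peak fraction.
#' @export
ssl_template_impulse <- function(peak, stance_duration) peak / 2 * stance_duration

# mean gait timing as a function of running speed (m/s)
.stride_duration <- function(speed) 0.80 - 0.045 * speed
.stance_duration <- function(speed) 0.40 - 0.050 * speed

#' Synthetic cohort generator configuration
#'
#' @param n_subjects Number of subjects.
#' @param speeds Running speeds in m/s (treadmill protocol grid).
#' @param trial_duration Trial length in seconds. Ignored when
#'   `steps_per_trial` is given.
#' @param steps_per_trial Optional number of complete right-foot steps per
#'   trial; when set, `trial_duration` is derived from the speed's stride time.
#' @param imu_rate IMU sampling rate in Hz.
#' @param grf_rate Force-plate sampling rate in Hz.
#' @param noise_scale Dimensionless multiplier on all measurement noise and on
#'   the anthropometric spread; 0 yields noiseless, population-mean data.
#' @param corrupt_fraction Fraction of steps tagged for artifact injection.
#' @param coupling Strength with which per-step latent gait parameters
#'   modulate both the IMU waveforms and the load templates (identifiability
#'   knob for the regression task).
#' @param sex_ratio Proportion of male subjects (cohort default 36/43).
#' @param seed Integer seed; fully determines the generated cohort.
#' @return Object of class `runload_config`.
#' @export
generator_config <- function(n_subjects = 10,
                             speeds = c(2.22, 2.78, 3.33),
                             trial_duration = 25,
                             steps_per_trial = NULL,
                             imu_rate = 240,
                             grf_rate = 1200,
                             noise_scale = 1,
                             corrupt_fraction = 0,
                             coupling = 1,
                             sex_ratio = 36 / 43,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, imu_rate > 0, grf_rate > 0,
            all(speeds > 0), trial_duration > 0,
            noise_scale >= 0, corrupt_fraction >= 0, corrupt_fraction <= 1,
            sex_ratio >= 0, sex_ratio <= 1)
  if (any(speeds < 2.0 | speeds > 4.0))
    warning("speeds outside the default protocol range [2.0, 4.0] m/s")
  structure(list(n_subjects = n_subjects, speeds = speeds,
                 trial_duration = trial_duration,
                 steps_per_trial = steps_per_trial,
                 imu_rate = imu_rate, grf_rate = grf_rate,
                 noise_scale = noise_scale,
                 corrupt_fraction = corrupt_fraction,
                 coupling = coupling, sex_ratio = sex_ratio,
                 seed = as.integer(seed)),
            class = "runload_config")
}

.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) > 0 && tries < 50L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1L
  }
  pmin(pmax(x, lower), upper)
}

#' Draw a synthetic subject profile
#'
#' Anthropometrics are drawn from per-sex normal distributions matching the
#' cohort summary statistics, truncated to physiologic ranges (mass 45--110
#' kg, height 150--210 cm, age 18--60 yr).
#'
#' @param subject_id Identifier string.
#' @param sex_ratio Probability of drawing a male subject.
#' @param noise_scale Multiplier on the anthropometric standard deviations;
#'   0 gives the population mean exactly.
#' @return One-row data frame: subject_id, mass_kg, sex, age_yr, height_cm,
#'   shoe_length_cm, sole_thickness_cm.
#' @export
generate_subject <- function(subject_id = "S01", sex_ratio = 36 / 43,
                             noise_scale = 1) {
  sex <- if (runif(1) < sex_ratio) "male" else "female"
  a <- .anthro[[sex]]
  ns <- noise_scale
  data.frame(
    subject_id = subject_id,
    mass_kg = .rtruncnorm(1, a$mass[1], a$mass[2] * ns, 45, 110),
    sex = sex,
    age_yr = .rtruncnorm(1, a$age[1], a$age[2] * ns, 18, 60),
    height_cm = .rtruncnorm(1, a$height[1], a$height[2] * ns, 150, 210),
    shoe_length_cm = .rtruncnorm(1, a$shoe_length[1], a$shoe_length[2] * ns, 20, 40),
    sole_thickness_cm = .rtruncnorm(1, a$sole_thickness[1], a$sole_thickness[2] * ns, 0.5, 8),
    stringsAsFactors = FALSE
  )
}

# piecewise-linear waveform from keypoints, evaluated on a sample grid
.keypoint_wave <- function(kt, kv, t_grid) {
  o <- order(kt)
  kt <- kt[o]; kv <- kv[o]
  keep <- c(TRUE, diff(kt) > 1e-9)
  approx(kt[keep], kv[keep], xout = t_grid, rule = 2)$y
}

#' Generate one synthetic treadmill trial
#'
#' Emits time-aligned pelvis/foot IMU streams (free acceleration in m/s² and
#' unit quaternions at `imu_rate`), right-foot vertical GRF and the four true
#' structure-specific load signals in N at `grf_rate`, plus per-step latent
#' parameters and ground-truth events. The foot vertical acceleration channel
#' (index 3) carries the impact morphology required by threshold gait-event
#' detection: a pre-contact dip, a steep rise through +0.18 g at initial
#' contact and an excursion below -0.25 g at toe-off. True IC/TO are defined
#' at the 50 N crossings of the generated vGRF.
#'
#' @param subject One-row subject data frame (see [generate_subject()]).
#' @param speed Running speed in m/s.
#' @param config A [generator_config()].
#' @return Object of class `runload_trial`.
#' @export
generate_trial <- function(subject, speed, config = generator_config()) {
  stopifnot(speed > 0)
  if (config$trial_duration <= 0) stop("trial_duration must be positive")
  mass <- subject$mass_kg
  bw <- mass * 9.81
  ns <- config$noise_scale
  cpl <- config$coupling
  fs_i <- config$imu_rate
  fs_g <- config$grf_rate

  stride0 <- .stride_duration(speed)
  stance0 <- .stance_duration(speed)
  if (!is.null(config$steps_per_trial)) {
    n_steps <- as.integer(config$steps_per_trial)
    duration <- 0.4 + (n_steps + 1) * stride0 + 0.3
  } else {
    duration <- config$trial_duration
    n_steps <- max(1L, floor((duration - 0.7) / stride0) - 1L)
  }

  # per-stride latent gait parameters (one spare stride so every counted step
  # has a following ipsilateral IC)
  n_strides <- n_steps + 1L
  s_amp <- rnorm(n_strides, 1, 0.05)
  s_imp <- s_amp * exp(rnorm(n_strides, 0, 0.03))
  strides <- stride0 * exp(rnorm(n_strides, 0, 0.01))
  stances <- pmin(stance0 * exp(rnorm(n_strides, 0, 0.012)), 0.95 * strides)
  t0 <- 0.3 + c(0, cumsum(strides[-n_strides]))

  sp <- .struct_params
  latent_load <- 1 + cpl * (s_amp - 1)
  peaks <- matrix(0, n_strides, 4, dimnames = list(NULL, .structures))
  tau_peaks <- matrix(0, n_strides, 4, dimnames = list(NULL, .structures))
  for (j in seq_len(4)) {
    eps <- exp(rnorm(n_strides, 0, 0.025))
    peaks[, j] <- sp$base[j] * (1 + sp$speed_slope[j] * (speed - 2.78)) *
      (mass / 75)^sp$mass_exp[j] * latent_load * eps
    tau_peaks[, j] <- pmin(pmax(sp$tau_peak[j] + sp$tau_speed[j] * (speed - 2.78) +
                                  rnorm(n_strides, 0, 0.01), 0.25), 0.70)
  }

  n_g <- ceiling(duration * fs_g)
  n_i <- ceiling(duration * fs_i)
  t_g <- (seq_len(n_g) - 1) / fs_g
  t_i <- (seq_len(n_i) - 1) / fs_i

  # --- vertical GRF and SSL truth at grf_rate -------------------------------
  vgrf <- numeric(n_g)
  ssl <- matrix(0, n_g, 4, dimnames = list(NULL, .structures))
  a_active <- (2.2 + 0.25 * (speed - 2.78)) * latent_load
  for (k in seq_len(n_strides)) {
    idx <- which(t_g >= t0[k] & t_g < t0[k] + stances[k])
    if (!length(idx)) next
    tau <- (t_g[idx] - t0[k]) / stances[k]
    f <- a_active[k] * sin(pi * tau) +
      0.5 * s_imp[k] * ifelse(tau < 0.26, sin(pi * pmin(tau / 0.26, 1))^2, 0)
    f <- f * bw + rnorm(length(idx), 0, 8 * ns)
    vgrf[idx] <- pmax(f, 0)
    for (j in seq_len(4)) {
      curve <- ssl_template(tau, peaks[k, j], tau_peaks[k, j]) * bw
      # load-proportional point noise (static-optimization-style chatter
      # scales with the instantaneous force, and vanishes with it at the
      # stance edges so clean steps respect the non-negativity filter)
      ssl[idx, j] <- pmax(curve * (1 + rnorm(length(idx), 0, 0.03 * ns)), 0)
    }
  }

  # true IC/TO at the 50 N crossings of the generated vGRF, using the same
  # maximal-run segmentation rule the reference pipeline applies, so stored
  # events are an unambiguous target for detector-tolerance tests
  seg_truth <- segment_steps_grf(vgrf, fs_g)
  ic_grf <- to_grf <- integer(n_strides)
  for (k in seq_len(n_strides)) {
    j <- which.min(abs((seg_truth$ic - 1) / fs_g - t0[k]))
    ic_grf[k] <- seg_truth$ic[j]
    to_grf[k] <- seg_truth$to[j]
  }

  # --- IMU streams at imu_rate ---------------------------------------------
  g <- 9.81
  impact <- (2.8 + 0.9 * (speed - 2.78)) * (1 + 0.9 * (s_imp - 1))

  kt <- kv <- numeric(0)   # foot vertical keypoints (g units)
  ka_t <- ka_v <- numeric(0)  # foot AP keypoints
  for (k in seq_len(n_strides)) {
    tc <- stances[k]
    kt <- c(kt, t0[k] + c(-0.12, -0.083, -0.02, 0, 0.029, 0.09,
                          0.5 * tc, tc - 0.042, tc, tc + 0.05))
    kv <- c(kv, c(0.05, 0.08, -0.30, -0.50, impact[k], 0.30,
                  0.35, 0.15, -0.65, 0.10))
    ka_t <- c(ka_t, t0[k] + c(-0.06, 0, 0.03, 0.5 * tc, tc, tc + 0.06))
    ka_v <- c(ka_v, c(0.02, -0.15, 0.40 * impact[k], -0.10, -0.30, 0.05))
  }
  foot_v <- .keypoint_wave(kt, kv, t_i) * g
  foot_ap <- .keypoint_wave(ka_t, ka_v, t_i) * g

  # per-sample stride membership for amplitude modulation
  stride_of <- findInterval(t_i, t0)
  stride_of[stride_of < 1] <- 1L
  amp_of <- s_amp[stride_of]
  phase <- (t_i - t0[stride_of]) / strides[stride_of]

  foot_ml <- 0.10 * (1 + 0.3 * (amp_of - 1)) * sin(2 * pi * phase) * g
  a_pv <- (0.30 + 0.08 * (speed - 2.78)) * (1 + 0.6 * cpl * (amp_of - 1)) *
    (mass / 75)^0.1
  pel_v <- a_pv * sin(2 * pi * 2 * phase) * g
  pel_ap <- 0.12 * (1 + 0.3 * cpl * (amp_of - 1)) * sin(2 * pi * 2 * phase + 1.0) * g
  pel_ml <- 0.08 * sin(2 * pi * phase + 0.5) * g

  noise_acc <- function(x) x + rnorm(length(x), 0, 0.025 * g * ns)
  foot_acc <- cbind(ap = noise_acc(foot_ap), ml = noise_acc(foot_ml),
                    v = noise_acc(foot_v))
  pelvis_acc <- cbind(ap = noise_acc(pel_ap), ml = noise_acc(pel_ml),
                      v = noise_acc(pel_v))

  # orientations: foot sagittal swing (about x), pelvis pitch (about y)
  a_th <- 0.5 * (1 + 0.25 * (speed - 2.78)) * (1 + 0.5 * cpl * (amp_of - 1))
  theta_f <- a_th * sin(2 * pi * phase + 0.8) + 0.3 * a_th * sin(4 * pi * phase)
  theta_p <- 0.06 * sin(2 * pi * 2 * phase)
  foot_quat <- cbind(cos(theta_f / 2), sin(theta_f / 2), 0, 0)
  pelvis_quat <- cbind(cos(theta_p / 2), 0, sin(theta_p / 2), 0)
  qn <- function(q) {
    q <- q + matrix(rnorm(length(q), 0, 0.002 * ns), nrow(q), 4)
    q / sqrt(rowSums(q^2))
  }
  foot_quat <- qn(foot_quat)
  pelvis_quat <- qn(pelvis_quat)
  # flip the sign of a contiguous block: same physical orientation sequence
  flip_from <- sample.int(n_i, 1)
  foot_quat[flip_from:n_i, ] <- -foot_quat[flip_from:n_i, ]

  # --- per-step truth metadata (first n_steps complete steps) ---------------
  ks <- seq_len(n_steps)
  corrupted <- runif(n_steps) < config$corrupt_fraction
  artifact <- rep(NA_character_, n_steps)
  artifact[corrupted] <- sample(c("dropout", "inflate", "amplitude"),
                                sum(corrupted), replace = TRUE)
  steps <- data.frame(
    step = ks,
    t0 = t0[ks],
    stride_s = strides[ks],
    stance_s = stances[ks],
    step_duration_s = strides[ks] / 2,
    ic_grf = ic_grf[ks],
    to_grf = to_grf[ks],
    stance_grf_s = (to_grf[ks] - ic_grf[ks]) / fs_g,
    s_amp = s_amp[ks],
    s_imp = s_imp[ks],
    corrupted = corrupted,
    artifact = artifact,
    side = "right",
    stringsAsFactors = FALSE
  )
  for (j in seq_len(4)) {
    steps[[paste0("peak_", .structures[j])]] <- peaks[ks, j]
    steps[[paste0("tau_peak_", .structures[j])]] <- tau_peaks[ks, j]
  }

  structure(list(
    subject_id = subject$subject_id,
    speed = speed,
    imu_rate = fs_i,
    grf_rate = fs_g,
    body_weight_n = bw,
    pelvis = list(acc = pelvis_acc, quat = pelvis_quat),
    foot = list(acc = foot_acc, quat = foot_quat),
    vgrf = vgrf,
    ssl = ssl,
    steps = steps,
    lag_s = 0
  ), class = "runload_trial")
}

#' Inject corruption artifacts into a trial
#'
#' Applies, to every step tagged `corrupted` in the trial metadata, the
#' artifact named in its `artifact` column: `dropout` zeroes a 22-sample
#' window of the foot acceleration channels inside the stance; `inflate`
#' appends a decaying >50 N tail to the vGRF after toe-off so the segmented
#' stance exceeds 0.5 s; `amplitude` scales the step's true load curves by 4
#' so the peak leaves the physiologic range.
#'
#' @param trial A `runload_trial`.
#' @param config The [generator_config()] used to create it.
#' @return The modified trial (identical input when nothing is tagged).
#' @export
inject_artifacts <- function(trial, config = generator_config()) {
  st <- trial$steps
  tagged <- which(st$corrupted)
  if (!length(tagged)) return(trial)
  fs_i <- trial$imu_rate
  fs_g <- trial$grf_rate
  for (k in tagged) {
    kind <- st$artifact[k]
    ic_t <- (st$ic_grf[k] - 1) / fs_g
    if (kind == "dropout") {
      i0 <- round(ic_t * fs_i) + 1L + 12L
      idx <- i0:min(i0 + 21L, nrow(trial$foot$acc))
      trial$foot$acc[idx, ] <- 0
    } else if (kind == "inflate") {
      n_tail <- round(0.35 * fs_g)
      idx <- st$to_grf[k]:min(st$to_grf[k] + n_tail - 1L, length(trial$vgrf))
      trial$vgrf[idx] <- 500 * (1 - seq_along(idx) / n_tail)
    } else if (kind == "amplitude") {
      idx <- st$ic_grf[k]:(st$to_grf[k] - 1L)
      trial$ssl[idx, ] <- trial$ssl[idx, ] * 4
    }
  }
  trial
}

#' Generate a full synthetic cohort
#'
#' Draws subjects, generates one trial per subject and speed, and applies
#' artifact injection. The configuration seed fully determines the output.
#'
#' @param config A [generator_config()].
#' @return Object of class `runload_cohort`: list with `subjects` (data
#'   frame), `trials` (list of `runload_trial`) and `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  set.seed(config$seed)
  subjects <- do.call(rbind, lapply(seq_len(config$n_subjects), function(i)
    generate_subject(sprintf("S%02d", i), config$sex_ratio, config$noise_scale)))
  trials <- list()
  for (i in seq_len(config$n_subjects)) {
    for (v in config$speeds) {
      tr <- generate_trial(subjects[i, ], v, config)
      tr <- inject_artifacts(tr, config)
      trials[[sprintf("%s_%0.2f", subjects$subject_id[i], v)]] <- tr
    }
  }
  structure(list(subjects = subjects, trials = trials, config = config),
            class = "runload_cohort")
}

#' @export
print.runload_cohort <- function(x, ...) {
  cat(sprintf("runload cohort: %d subjects x %d speeds (%s m/s), %d trials\n",
              nrow(x$subjects), length(x$config$speeds),
              paste(x$config$speeds, collapse = ", "), length(x$trials)))
  invisible(x)
}

#' @export
print.runload_trial <- function(x, ...) {
  cat(sprintf("runload trial: subject %s @ %.2f m/s, %d steps, %.1f s\n",
              x$subject_id, x$speed, nrow(x$steps),
              length(x$vgrf) / x$grf_rate))
  invisible(x)
}
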