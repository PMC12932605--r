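# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

# small clean cohort reused across imu / ssl / feature tests
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(generator_config(n_subjects = 3, speeds = c(2.22, 3.33),
                                     steps_per_trial = 12, seed = 402))
  })
}

small_steps <- function() {
  fixture("small_steps", function() collect_step_data(small_cohort(), "dual"))
}

# cohort with injected artifacts for the exclusion audit
corrupt_cohort <- function() {
  fixture("corrupt_cohort", function() {
    generate_cohort(generator_config(n_subjects = 4, speeds = c(2.22, 2.78, 3.33),
                                     steps_per_trial = 20, corrupt_fraction = 0.1,
                                     seed = 907))
  })
}

# map GRF-segmented IC indices onto the generator's truth table by nearest
# true IC; returns truth row indices (NA when unmatched)
match_truth_steps <- function(ic_indices, trial) {
  if (is.data.frame(ic_indices)) ic_indices <- ic_indices$ic_grf
  vapply(ic_indices, function(ic) {
    d <- abs(trial$steps$ic_grf - ic)
    j <- which.min(d)
    if (d[j] <= 0.05 * trial$grf_rate) j else NA_integer_
  }, integer(1))
}

# triangular impact train with analytically known threshold crossings
impact_train <- function(n_steps = 5, period = 170, fs = 240) {
  x <- rep(0.05, 60)
  for (k in seq_len(n_steps)) {
    x <- c(x, seq(0.05, -0.6, length.out = 12),   # pre-contact dip
           seq(0.3, 3, length.out = 8),           # impact rise (crosses 0.18)
           seq(2.8, 0.3, length.out = 20),        # decay
           rep(0.3, 40),                          # mid-stance
           seq(0.28, -0.7, length.out = 14),      # toe-off trough
           seq(-0.6, 0.05, length.out = 12),
           rep(0.05, period - 106))
  }
  x
}

# brute-force sample entropy oracle: literal template counting
sampen_oracle <- function(x, m = 2L, r = 0.2 * sd(x)) {
  n <- length(x)
  nt <- n - m
  count <- function(len) {
    cnt <- 0L
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= r)
          cnt <- cnt + 1L
      }
    }
    cnt
  }
  b <- count(m)
  a <- count(m + 1L)
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

# brute-force gait-event oracle: literal sample-by-sample scan of the
# documented crossing-and-constraint rules
detect_events_oracle <- function(x, w = 5L, ic_thr = 0.18, to_thr = -0.25,
                                 relax_step = 0.05, relax_max = -0.05) {
  n <- length(x)
  ics <- integer(0)
  for (i in seq(2L * w + 1L, n - w)) {
    if (x[i] >= ic_thr && x[i - 1] < ic_thr &&
        min(x[(i - 2L * w):(i - 1L)]) <= -0.05 && x[i + w] > x[i])
      ics <- c(ics, i)
  }
  out <- NULL
  for (j in seq_along(ics)) {
    i <- ics[j]
    lim <- if (j < length(ics)) ics[j + 1L] - 1L else n
    thr <- to_thr
    found <- NA_integer_
    while (is.na(found) && thr <= relax_max + 1e-12) {
      for (k in (i + 1L):lim) {
        if (k > w && x[k] <= thr && x[k - 1] > thr && x[k - w] > x[k]) {
          found <- k
          break
        }
      }
      if (is.na(found)) thr <- thr + relax_step
    }
    if (!is.na(found))
      out <- rbind(out, data.frame(ic = i, to = found, to_threshold = thr))
  }
  if (is.null(out)) data.frame(ic = integer(0), to = integer(0),
                               to_threshold = numeric(0)) else out
}

# quaternion stream for a constant-rate rotation about a fixed axis
rotation_quat_stream <- function(rate_rad_s, axis, fs, t_end) {
  t <- seq(0, t_end, by = 1 / fs)
  axis <- axis / sqrt(sum(axis^2))
  ang <- rate_rad_s * t / 2
  cbind(cos(ang), sin(ang) %o% axis)
}

quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# central-difference rotation-matrix oracle for the body-frame angular rate:
# [omega]_x = R^T dR/dt (skew-symmetric part)
angular_velocity_rotmat_oracle <- function(quat, dt) {
  n <- nrow(quat)
  t(vapply(2:(n - 1), function(i) {
    R0 <- quat_to_rotmat(quat[i, ])
    dR <- (quat_to_rotmat(quat[i + 1, ]) - quat_to_rotmat(quat[i - 1, ])) / (2 * dt)
    S <- t(R0) %*% dR
    c(S[3, 2] - S[2, 3], S[1, 3] - S[3, 1], S[2, 1] - S[1, 2]) / 2
  }, numeric(3)))
}
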