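# Quaternion convention: rows (w, x, y, z), Hamilton product, unit norm.

# zero-phase filtering with odd-symmetric edge extension (the padding scheme
# scipy's filtfilt uses), which suppresses the start/end transients of a
# plain forward-backward pass
.filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(bf, ext)
  y[(pad + 1):(pad + n)]
}

.quat_conjugate <- function(q) cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])

# row-wise Hamilton product a (x) b for n x 4 matrices
.quat_multiply <- function(a, b) {
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w, x, y, z)
}

#' Angular velocity from a quaternion stream
#'
#' Forward-difference rate in the sensor frame:
#' `omega(t) = (2 / dt) * vec( conj(q(t)) (x) q(t + dt) )`.
#' The relative quaternion's sign is canonicalized (scalar part made
#' non-negative) before taking the vector part, so streams where `q` and `-q`
#' alternate — the same physical orientation — yield zero rate.
#'
#' @param quat T x 4 matrix of unit quaternions (w, x, y, z). Rows are
#'   renormalized; norms off unity by more than 1e-3 are an error, as are
#'   zero-norm rows.
#' @param dt Sample interval in seconds (1 / imu_rate).
#' @return List with `omega`, a (T-1) x 3 matrix in rad/s timestamped at the
#'   left sample of each forward difference, and `dt`.
#' @export
angular_velocity <- function(quat, dt) {
  stopifnot(is.matrix(quat), ncol(quat) == 4, dt > 0)
  if (nrow(quat) < 2) stop("need at least two quaternion samples")
  norms <- sqrt(rowSums(quat^2))
  if (any(norms == 0)) stop("zero-norm quaternion row")
  if (any(abs(norms - 1) > 1e-3)) stop("quaternion rows deviate from unit norm")
  q <- quat / norms
  n <- nrow(q)
  p <- .quat_multiply(.quat_conjugate(q[-n, , drop = FALSE]),
                      q[-1, , drop = FALSE])
  flip <- p[, 1] < 0
  p[flip, ] <- -p[flip, , drop = FALSE]
  omega <- (2 / dt) * p[, 2:4, drop = FALSE]
  colnames(omega) <- c("x", "y", "z")
  list(omega = omega, dt = dt)
}

#' Zero-phase low-pass filtering of acceleration streams
#'
#' Fifth-order Butterworth, 40 Hz cutoff, applied forward-backward
#' (zero-phase) per channel so gait-event timing is not lag-shifted.
#'
#' @param acc T x C matrix (or vector) in m/s².
#' @param rate Sampling rate in Hz; must exceed 80 Hz so the cutoff sits
#'   below Nyquist.
#' @param cutoff Cutoff frequency in Hz (default 40).
#' @param order Filter order (default 5).
#' @return Filtered matrix, same dimensions as the input.
#' @export
filter_acceleration <- function(acc, rate, cutoff = 40, order = 5) {
  if (rate <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff")
  vec <- is.null(dim(acc))
  m <- if (vec) matrix(acc, ncol = 1) else acc
  if (nrow(m) < 3 * (2 * order + 1))
    stop("stream shorter than the filter warm-up length")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  pad <- as.integer(ceiling(6 * rate / cutoff))
  out <- apply(m, 2, function(col) .filtfilt_padded(bf, col, pad))
  if (vec) as.numeric(out) else out
}

#' Detect initial-contact and toe-off events from vertical acceleration
#'
#' IC is an upward crossing of `+0.18` g that follows a pre-contact dip (the
#' minimum over the `2 * window` preceding samples at or below -0.05 g) and
#' is followed by a net rise (`x[i + window] > x[i]`). TO is the first
#' downward crossing of `-0.25` g after the matched IC with a net decrease
#' into the trough (`x[j - window] > x[j]`). When no TO is found before the
#' next IC candidate, the TO threshold is relaxed in +0.05 g steps up to
#' -0.05 g; ICs still unmatched are dropped.
#'
#' @param vacc Vertical acceleration in g units (divide m/s² by 9.81 first).
#' @param rate Sampling rate in Hz.
#' @param ic_threshold IC threshold in g (default +0.18).
#' @param to_threshold Initial TO threshold in g (default -0.25).
#' @param window Constraint window in samples (default 5, about 21 ms at
#'   240 Hz).
#' @param relax_step TO threshold relaxation increment in g (default 0.05).
#' @param relax_max Least-negative TO threshold tried (default -0.05).
#' @return Data frame with columns `ic`, `to` (1-based sample indices) and
#'   `to_threshold` (the threshold that matched each event).
#' @export
detect_gait_events <- function(vacc, rate, ic_threshold = 0.18,
                               to_threshold = -0.25, window = 5L,
                               relax_step = 0.05, relax_max = -0.05) {
  if (!length(vacc)) stop("empty signal")
  if (rate <= 0) stop("rate must be positive")
  n <- length(vacc)
  w <- as.integer(window)
  cross_up <- which(vacc[-1] >= ic_threshold & vacc[-n] < ic_threshold) + 1L
  ic_cand <- cross_up[cross_up > 2L * w & cross_up + w <= n]
  ic_cand <- ic_cand[vapply(ic_cand, function(i) {
    min(vacc[(i - 2L * w):(i - 1L)]) <= -0.05 && vacc[i + w] > vacc[i]
  }, logical(1))]
  if (!length(ic_cand))
    return(data.frame(ic = integer(0), to = integer(0),
                      to_threshold = numeric(0)))
  ic_out <- to_out <- integer(0)
  thr_out <- numeric(0)
  for (j in seq_along(ic_cand)) {
    i <- ic_cand[j]
    lim <- if (j < length(ic_cand)) ic_cand[j + 1L] - 1L else n
    thr <- to_threshold
    found <- NA_integer_
    while (is.na(found) && thr <= relax_max + 1e-12) {
      rng <- (i + 1L):lim
      dn <- rng[vacc[rng] <= thr & vacc[rng - 1L] > thr]
      dn <- dn[dn > w]
      dn <- dn[vapply(dn, function(k) vacc[k - w] > vacc[k], logical(1))]
      if (length(dn)) found <- dn[1] else thr <- thr + relax_step
    }
    if (!is.na(found)) {
      ic_out <- c(ic_out, i)
      to_out <- c(to_out, found)
      thr_out <- c(thr_out, thr)
    }
  }
  data.frame(ic = ic_out, to = to_out, to_threshold = thr_out)
}

#' Synchronize two acceleration streams by cross-correlation
#'
#' Returns the integer lag (in samples) that maximizes the normalized
#' cross-correlation between the reference and the target stream. A positive
#' lag means the target is delayed by that many samples relative to the
#' reference (`target[i] ~ reference[i - lag]`). Ties are broken toward the
#' smaller absolute lag.
#'
#' @param reference,target Numeric vectors at a common sampling rate.
#' @param max_lag Maximum absolute lag searched, in samples; must be smaller
#'   than half the shorter stream.
#' @return Integer lag in samples.
#' @export
synchronize <- function(reference, target, max_lag) {
  n <- min(length(reference), length(target))
  stopifnot(max_lag >= 0, max_lag < n / 2)
  if (sd(reference) == 0 || sd(target) == 0)
    stop("cannot synchronize constant (zero-variance) signals")
  lags <- -max_lag:max_lag
  score <- vapply(lags, function(l) {
    if (l >= 0) {
      a <- reference[1:(n - l)]; b <- target[(1 + l):n]
    } else {
      a <- reference[(1 - l):n]; b <- target[1:(n + l)]
    }
    if (sd(a) == 0 || sd(b) == 0) return(-Inf)
    cor(a, b)
  }, numeric(1))
  best <- max(score)
  cand <- lags[score >= best - 1e-12]
  cand[which.min(abs(cand))]
}
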