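#' Filter a load signal and normalize to body weight
#'
#' Zero-phase fifth-order Butterworth low-pass at 20 Hz, then division by
#' body weight. Tiny negative values introduced by filtering (above -0.01 BW)
#' are clamped to zero; larger negatives are preserved so the range exclusion
#' can catch them.
#'
#' @param ssl_n Load signal in N.
#' @param rate Sampling rate in Hz; must exceed 40 Hz.
#' @param body_weight Body weight in N (mass in kg times 9.81).
#' @param cutoff Cutoff frequency in Hz (default 20).
#' @return Signal in BW, same length.
#' @export
filter_and_normalize_ssl <- function(ssl_n, rate, body_weight, cutoff = 20) {
  if (rate <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff")
  stopifnot(body_weight > 0)
  bf <- signal::butter(5, cutoff / (rate / 2), type = "low")
  x <- .filtfilt_padded(bf, ssl_n, as.integer(ceiling(6 * rate / cutoff))) / body_weight
  x[x < 0 & x > -0.01] <- 0
  x
}

#' Segment stance phases from vertical GRF at the 50 N threshold
#'
#' A stance is a maximal run of samples with vGRF >= 50 N; IC is its first
#' sample, TO the sample after its last (half-open `[ic, to)`). Runs shorter
#' than 10 ms are discarded as threshold chatter.
#'
#' @param vgrf Vertical GRF in N (non-negative).
#' @param rate Sampling rate in Hz.
#' @param threshold Segmentation threshold in N (default 50).
#' @return Data frame with 1-based columns `ic`, `to`.
#' @export
segment_steps_grf <- function(vgrf, rate, threshold = 50) {
  above <- vgrf >= threshold
  if (!any(above)) return(data.frame(ic = integer(0), to = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= ceiling(0.010 * rate)
  data.frame(ic = starts[keep], to = ends[keep] + 1L)
}

#' Match GRF-detected steps to acceleration-detected steps
#'
#' Greedy one-to-one nearest-IC matching within a time tolerance: candidate
#' pairs are accepted in order of increasing IC time difference. GRF steps
#' without an acceleration event within tolerance are returned unmatched with
#' reason `"unmatched"`.
#'
#' @param grf_ic_times IC times of GRF-segmented steps, in seconds.
#' @param acc_ic_times IC times of acceleration-detected steps, in seconds.
#' @param tolerance_s Matching tolerance in seconds (default 0.05).
#' @return Data frame with one row per GRF step: `grf_step`, `acc_step`
#'   (NA when unmatched), `offset_s` and `reason`.
#' @export
match_steps <- function(grf_ic_times, acc_ic_times, tolerance_s = 0.05) {
  ng <- length(grf_ic_times)
  na <- length(acc_ic_times)
  out <- data.frame(grf_step = seq_len(ng), acc_step = NA_integer_,
                    offset_s = NA_real_, reason = NA_character_)
  if (ng == 0) return(out)
  if (na > 0) {
    pairs <- expand.grid(g = seq_len(ng), a = seq_len(na))
    pairs$d <- abs(grf_ic_times[pairs$g] - acc_ic_times[pairs$a])
    pairs <- pairs[pairs$d <= tolerance_s, , drop = FALSE]
    pairs <- pairs[order(pairs$d), , drop = FALSE]
    used_a <- logical(na)
    for (r in seq_len(nrow(pairs))) {
      g <- pairs$g[r]; a <- pairs$a[r]
      if (is.na(out$acc_step[g]) && !used_a[a]) {
        out$acc_step[g] <- a
        out$offset_s[g] <- grf_ic_times[g] - acc_ic_times[a]
        used_a[a] <- TRUE
      }
    }
  }
  out$reason[is.na(out$acc_step)] <- "unmatched"
  out
}

#' Exclusion-rule configuration
#'
#' @param stance_range Accepted stance-phase duration range in seconds.
#' @param step_range Accepted total step duration range in seconds.
#' @param peak_range Accepted SSL peak range in BW (open lower, closed upper).
#' @param negative_floor Most negative tolerated SSL value in BW.
#' @param dropout_run Minimum run of identical acceleration samples flagged
#'   as signal dropout.
#' @return List of exclusion parameters.
#' @export
exclusion_config <- function(stance_range = c(0.15, 0.5),
                             step_range = c(0.21, 0.6),
                             peak_range = c(0.5, 15),
                             negative_floor = -0.01,
                             dropout_run = 20L) {
  list(stance_range = stance_range, step_range = step_range,
       peak_range = peak_range, negative_floor = negative_floor,
       dropout_run = as.integer(dropout_run))
}

.max_identical_run <- function(x) {
  if (length(x) < 2) return(length(x))
  max(rle(x)$lengths)
}

#' Apply step exclusion rules
#'
#' Rules are evaluated in a fixed order and the first failing rule is
#' reported: stance duration outside `[0.15, 0.5]` s; step duration outside
#' `[0.21, 0.6]` s; signal dropout (a run of >= 20 identical samples in any
#' raw acceleration channel during stance); SSL out of the expected range
#' (peak outside `(0.5, 15]` BW or any value below -0.01 BW).
#'
#' @param stance_duration Stance duration in seconds.
#' @param step_duration Step duration in seconds (NA skips the rule).
#' @param acc_segment Raw stance-phase acceleration segment, T x C (optional).
#' @param ssl_curves Stance-phase load curves in BW, T x 4 (optional).
#' @param cfg An [exclusion_config()].
#' @return List with `accepted` (logical) and `reason` (NA when accepted).
#' @export
apply_exclusions <- function(stance_duration, step_duration = NA,
                             acc_segment = NULL, ssl_curves = NULL,
                             cfg = exclusion_config()) {
  fail <- function(reason) list(accepted = FALSE, reason = reason)
  if (stance_duration < cfg$stance_range[1] ||
      stance_duration > cfg$stance_range[2]) return(fail("stance_duration"))
  if (!is.na(step_duration) &&
      (step_duration < cfg$step_range[1] || step_duration > cfg$step_range[2]))
    return(fail("step_duration"))
  if (!is.null(acc_segment)) {
    runs <- apply(as.matrix(acc_segment), 2, .max_identical_run)
    if (any(runs >= cfg$dropout_run)) return(fail("corruption"))
  }
  if (!is.null(ssl_curves)) {
    m <- as.matrix(ssl_curves)
    peaks <- apply(m, 2, max)
    if (any(peaks <= cfg$peak_range[1]) || any(peaks > cfg$peak_range[2]) ||
        any(m < cfg$negative_floor)) return(fail("ssl_range"))
  }
  list(accepted = TRUE, reason = NA_character_)
}

#' Time-normalize a curve to 100 samples
#'
#' Linear interpolation onto 100 equally spaced points spanning the original
#' support `[0, T - 1]`; endpoints are preserved exactly.
#'
#' @param curve Numeric vector, length >= 2.
#' @param n_out Number of output samples (default 100).
#' @return Numeric vector of length `n_out`.
#' @export
time_normalize <- function(curve, n_out = 100L) {
  n <- length(curve)
  if (n < 2) stop("need at least two samples to time-normalize")
  approx(x = seq_len(n) - 1, y = curve,
         xout = seq(0, n - 1, length.out = n_out))$y
}

#' Peak of a stance-phase load curve
#'
#' @param curve Load curve in BW.
#' @return List with `peak` (BW) and `frame`, the 0-based index of the
#'   earliest maximum (retained for the loading-rate interval).
#' @export
ssl_peak <- function(curve) {
  i <- which.max(curve)
  list(peak = curve[i], frame = i - 1L)
}

#' Impulse of a stance-phase load curve
#'
#' Rectangular sum over the 100 time-normalized frames (BW·frame), divided by
#' the effective sampling rate of the normalized curve, `100 /
#' stance_duration` frames per second, giving BW·s.
#'
#' @param curve Time-normalized load curve in BW (100 samples).
#' @param stance_duration Stance duration in seconds.
#' @return Impulse in BW·s.
#' @export
ssl_impulse <- function(curve, stance_duration) {
  stopifnot(stance_duration > 0)
  sum(curve) / (length(curve) / stance_duration)
}

# round half away from zero
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Structure-specific loading-rate interval configuration
#'
#' Achilles tendon, patellar tendon and ankle contact force use 20 %--80 % of
#' the interval from initial contact to the peak; knee contact force uses
#' 10 %--40 % of the interval from initial contact to toe-off.
#'
#' @return Data frame with columns `structure`, `p_lower`, `p_upper`,
#'   `interval_kind`.
#' @export
characteristic_config <- function() {
  data.frame(
    structure = .structures,
    p_lower = c(0.2, 0.2, 0.2, 0.1),
    p_upper = c(0.8, 0.8, 0.8, 0.4),
    interval_kind = c("ic_to_peak", "ic_to_peak", "ic_to_peak", "ic_to_to"),
    stringsAsFactors = FALSE
  )
}

#' Average loading rate of a stance-phase load curve
#'
#' `(SSL at p_upper - SSL at p_lower) / (frame difference / effective rate)`
#' where the interval is IC-to-peak or IC-to-TO, percentile frames are
#' rounded half away from zero, and the effective rate is `100 /
#' stance_duration`.
#'
#' @param curve Time-normalized load curve in BW (100 samples).
#' @param stance_duration Stance duration in seconds.
#' @param p_lower,p_upper Interval fractions, `0 <= p_lower < p_upper <= 1`.
#' @param interval_kind `"ic_to_peak"` or `"ic_to_to"`.
#' @return Loading rate in BW/s, or NA when the rounded frames coincide
#'   (degenerate early peak).
#' @export
ssl_loading_rate <- function(curve, stance_duration, p_lower, p_upper,
                             interval_kind = c("ic_to_peak", "ic_to_to")) {
  interval_kind <- match.arg(interval_kind)
  stopifnot(stance_duration > 0, p_lower >= 0, p_upper <= 1, p_lower < p_upper)
  n <- length(curve)
  len <- if (interval_kind == "ic_to_peak") ssl_peak(curve)$frame else n - 1L
  f_lo <- .round_half_away(p_lower * len)
  f_hi <- .round_half_away(p_upper * len)
  if (f_hi == f_lo) return(NA_real_)
  eff_rate <- n / stance_duration
  (curve[f_hi + 1L] - curve[f_lo + 1L]) / ((f_hi - f_lo) / eff_rate)
}

#' All three characteristics of one load curve
#'
#' @param curve Time-normalized load curve in BW (100 samples).
#' @param stance_duration Stance duration in seconds.
#' @param structure One of the four structure names.
#' @return Named vector: `peak` (BW), `impulse` (BW·s), `loading_rate` (BW/s).
#' @export
ssl_characteristics <- function(curve, stance_duration, structure) {
  cfg <- characteristic_config()
  row <- cfg[cfg$structure == structure, ]
  if (!nrow(row)) stop("unknown structure: ", structure)
  c(peak = ssl_peak(curve)$peak,
    impulse = ssl_impulse(curve, stance_duration),
    loading_rate = ssl_loading_rate(curve, stance_duration, row$p_lower,
                                    row$p_upper, row$interval_kind))
}
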