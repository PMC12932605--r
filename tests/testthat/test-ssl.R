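test_that("load filtering and normalization have unit DC gain and correct units", {
  x <- rep(800, 1200)
  out <- filter_and_normalize_ssl(x, 1200, body_weight = 800)
  expect_equal(out, rep(1, 1200), tolerance = 1e-4)
  # body weight bookkeeping: mass * 9.81
  expect_equal(79.8 * 9.81, 782.838)
  expect_error(filter_and_normalize_ssl(x, 30, 800), "cutoff")
  expect_error(filter_and_normalize_ssl(x, 1200, 0), "body_weight > 0")
})

test_that("20 Hz filtering attenuates a 100 Hz ripple on a stance bump", {
  fs <- 1200
  t <- seq(0, 0.5, by = 1 / fs)
  bump <- 2000 * sin(pi * t / 0.5)
  ripple <- 150 * sin(2 * pi * 100 * t)
  out <- filter_and_normalize_ssl(bump + ripple, fs, 800)
  clean <- filter_and_normalize_ssl(bump, fs, 800)
  mid <- 150:450
  resid_ripple <- max(abs(out[mid] - clean[mid]))
  expect_lt(resid_ripple, (150 / 800) / 10)
})

test_that("GRF segmentation follows the 50 N crossing with half-open bounds", {
  vgrf <- rep(0, 600)
  vgrf[100:399] <- 600
  seg <- segment_steps_grf(vgrf, 1200)
  expect_equal(seg$ic, 100)
  expect_equal(seg$to, 400)
  expect_equal(nrow(segment_steps_grf(rep(0, 500), 1200)), 0)
  # sub-10 ms chatter discarded
  chatter <- rep(0, 200); chatter[50:54] <- 100
  expect_equal(nrow(segment_steps_grf(chatter, 1200)), 0)
})

test_that("segmented stance durations match generator truth within one sample", {
  coh <- small_cohort()
  tr <- coh$trials[[1]]
  seg <- segment_steps_grf(tr$vgrf, tr$grf_rate)
  truth <- match_truth_steps(seg$ic, tr)
  ok <- !is.na(truth)
  expect_gt(mean(ok), 0.9)
  expect_true(all(abs(seg$ic[ok] - tr$steps$ic_grf[truth[ok]]) <= 1))
  expect_true(all(abs(seg$to[ok] - tr$steps$to_grf[truth[ok]]) <= 1))
})

test_that("step matching is greedy one-to-one within tolerance", {
  grf <- c(0.5, 1.2, 1.9)
  m <- match_steps(grf, grf)
  expect_equal(m$acc_step, 1:3)
  expect_true(all(m$offset_s == 0))

  m2 <- match_steps(c(0.5, 1.2), c(0.51, 5.0))
  expect_equal(m2$acc_step, c(1L, NA))
  expect_equal(m2$reason, c(NA, "unmatched"))

  set.seed(31)
  jitter <- runif(20, -0.02, 0.02)
  grf_t <- seq(0.5, by = 0.7, length.out = 20)
  m3 <- match_steps(grf_t, grf_t + jitter)
  expect_true(all(!is.na(m3$acc_step)))
  expect_equal(m3$acc_step, 1:20)   # exhaustive pairing on well-separated steps
})

test_that("exclusion rules fire in documented order with first failing reason", {
  ok_curves <- matrix(rep(ssl_template(seq(0, 1, length.out = 50), 3, 0.5), 4), ncol = 4)
  expect_equal(apply_exclusions(0.55, 0.35, NULL, ok_curves)$reason, "stance_duration")
  expect_equal(apply_exclusions(0.10, 0.35, NULL, ok_curves)$reason, "stance_duration")
  expect_equal(apply_exclusions(0.30, 0.65, NULL, ok_curves)$reason, "step_duration")
  acc_drop <- matrix(rnorm(300), 100, 3)
  acc_drop[40:60, 2] <- 1.23
  expect_equal(apply_exclusions(0.30, 0.35, acc_drop, ok_curves)$reason, "corruption")
  hot <- ok_curves * 8   # peak 24 BW
  expect_equal(apply_exclusions(0.30, 0.35, NULL, hot)$reason, "ssl_range")
  weak <- ok_curves * 0.1
  expect_equal(apply_exclusions(0.30, 0.35, NULL, weak)$reason, "ssl_range")
  # stance violation takes precedence even when SSL is also out of range
  expect_equal(apply_exclusions(0.55, 0.35, acc_drop, hot)$reason, "stance_duration")

  acc_ok <- matrix(rnorm(300), 100, 3)
  v <- apply_exclusions(0.30, 0.40, acc_ok, ok_curves)
  expect_true(v$accepted)
  expect_true(is.na(v$reason))
  # deterministic and idempotent: identical verdict on re-evaluation
  expect_identical(v, apply_exclusions(0.30, 0.40, acc_ok, ok_curves))
  expect_identical(apply_exclusions(0.55, 0.65, acc_drop, hot),
                   apply_exclusions(0.55, 0.65, acc_drop, hot))
})

test_that("time normalization is exact for linear ramps and idempotent at 100", {
  expect_equal(time_normalize(rep(2.5, 64)), rep(2.5, 100))
  ramp <- seq(0, 1, length.out = 73)
  out <- time_normalize(ramp)
  expect_equal(out, seq(0, 1, length.out = 100), tolerance = 1e-12)
  expect_equal(out[1], 0)
  expect_equal(out[100], 1)
  x <- rnorm(100)
  expect_equal(time_normalize(x), x, tolerance = 1e-12)
  expect_error(time_normalize(3), "two samples")
})

test_that("peak takes the earliest maximum and retains its frame", {
  curve <- ssl_template(seq(0, 1, length.out = 100), 4.2, 0.5)
  p <- ssl_peak(curve)
  expect_equal(p$peak, 4.2, tolerance = 1e-3)   # 100-point grid straddles the true peak
  mono <- seq(0, 2, length.out = 100)
  expect_equal(ssl_peak(mono)$frame, 99L)
  tied <- c(1, 5, 5, 2)
  expect_equal(ssl_peak(tied)$frame, 1L)
})

test_that("impulse matches closed forms and is linear", {
  expect_equal(ssl_impulse(rep(2, 100), 0.25), 0.5)
  expect_equal(ssl_impulse(rep(0, 100), 0.3), 0)
  curve <- ssl_template(seq(0, 1, length.out = 100), 6.5, 0.52)
  analytic <- ssl_template_impulse(6.5, 0.28)
  expect_equal(ssl_impulse(curve, 0.28), analytic, tolerance = 0.02)
  # linearity in amplitude and stance duration
  expect_equal(ssl_impulse(3 * curve, 0.28), 3 * ssl_impulse(curve, 0.28))
  expect_equal(ssl_impulse(curve, 0.56), 2 * ssl_impulse(curve, 0.28))
})

test_that("loading rate matches the linear-ramp closed form", {
  curve <- c(seq(0, 1, length.out = 51), seq(1, 0, length.out = 50)[-1])
  expect_equal(length(curve), 100)
  lr <- ssl_loading_rate(curve, 0.3, 0.2, 0.8, "ic_to_peak")
  # peak frame 50; frames 10 and 40 hold 0.2 and 0.8 BW; dt = 30 / (100/0.3)
  expect_equal(lr, (0.8 - 0.2) / (30 / (100 / 0.3)), tolerance = 1e-12)
  expect_equal(lr, 6.667, tolerance = 1e-3)
  expect_equal(ssl_loading_rate(rep(1, 100), 0.3, 0.1, 0.4, "ic_to_to"), 0)
  # halving stance duration doubles the rate
  expect_equal(ssl_loading_rate(curve, 0.15, 0.2, 0.8, "ic_to_peak"), 2 * lr)
  # degenerate early peak
  spike <- c(5, rep(0, 99))
  expect_true(is.na(ssl_loading_rate(spike, 0.3, 0.2, 0.8, "ic_to_peak")))
})

test_that("characteristics recover generator template values on a noiseless cohort", {
  coh <- fixture("noiseless_cohort", function()
    generate_cohort(generator_config(n_subjects = 2, speeds = c(2.22, 3.33),
                                     steps_per_trial = 8, noise_scale = 0,
                                     seed = 515)))
  sd0 <- collect_step_data(coh, "dual")
  # map accepted steps back to generator truth
  for (st in c("achilles", "knee")) {
    rel_err <- numeric(0)
    imp_err <- numeric(0)
    for (id in names(coh$trials)) {
      tr <- coh$trials[[id]]
      idx <- which(sd0$meta$subject_id == tr$subject_id &
                     sd0$meta$speed == tr$speed)
      if (!length(idx)) next
      truth <- match_truth_steps(sd0$meta$ic_grf[idx], tr)
      ok <- !is.na(truth)
      peaks_hat <- apply(sd0$Y[[st]][idx[ok], , drop = FALSE], 1, max)
      peaks_true <- tr$steps[[paste0("peak_", st)]][truth[ok]]
      rel_err <- c(rel_err, abs(peaks_hat - peaks_true) / peaks_true)
      imp_hat <- vapply(which(ok), function(j)
        ssl_impulse(sd0$Y[[st]][idx[j], ], sd0$meta$stance_duration[idx[j]]),
        numeric(1))
      imp_true <- ssl_template_impulse(peaks_true,
                                       tr$steps$stance_s[truth[ok]])
      imp_err <- c(imp_err, abs(imp_hat - imp_true) / imp_true)
    }
    expect_gt(length(rel_err), 10)
    expect_lt(max(rel_err), 0.02)
    expect_lt(max(imp_err), 0.02)
  }
})

test_that("higher speed yields larger mean template peaks by construction", {
  # direct evaluation of the generator's amplitude model
  sp <- structure_parameters()
  for (j in seq_len(nrow(sp))) {
    peak_slow <- sp$base[j] * (1 + sp$speed_slope[j] * (2.22 - 2.78))
    peak_fast <- sp$base[j] * (1 + sp$speed_slope[j] * (3.33 - 2.78))
    expect_gt(peak_fast, peak_slow)
  }
  # and in generated data
  coh <- small_cohort()
  sd1 <- small_steps()
  peaks <- apply(sd1$Y$achilles, 1, max)
  expect_gt(mean(peaks[sd1$meta$speed == 3.33]),
            mean(peaks[sd1$meta$speed == 2.22]))
})
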