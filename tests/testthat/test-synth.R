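test_that("subject anthropometrics follow the cohort distributions", {
  set.seed(101)
  males <- do.call(rbind, lapply(1:1000, function(i)
    generate_subject(paste0("M", i), sex_ratio = 1)))
  expect_true(all(males$sex == "male"))
  # distributional check over 1,000 draws (SE of mean ~ 0.3 kg)
  expect_equal(mean(males$mass_kg), 79.8, tolerance = 0.02)
  expect_equal(sd(males$mass_kg), 9.5, tolerance = 0.10)
  expect_equal(mean(males$height_cm), 186.3, tolerance = 0.01)
  expect_true(all(males$mass_kg >= 45 & males$mass_kg <= 110))
  expect_true(all(males$height_cm >= 150 & males$height_cm <= 210))
  expect_true(all(males$age_yr >= 18))

  set.seed(102)
  females <- do.call(rbind, lapply(1:500, function(i)
    generate_subject(paste0("F", i), sex_ratio = 0)))
  expect_equal(mean(females$mass_kg), 63.2, tolerance = 0.02)
  expect_equal(mean(females$height_cm), 173.1, tolerance = 0.02)
})

test_that("zero noise scale collapses anthropometrics to the population means", {
  set.seed(103)
  s <- generate_subject("A", sex_ratio = 1, noise_scale = 0)
  expect_equal(s$mass_kg, 79.8)
  expect_equal(s$height_cm, 186.3)
  expect_equal(s$age_yr, 24.4)
})

test_that("the generator is deterministic in its seed", {
  cfg <- generator_config(n_subjects = 2, speeds = 2.78, steps_per_trial = 5,
                          seed = 77, corrupt_fraction = 0.2)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(generator_config(n_subjects = 2, speeds = 2.78,
                                         steps_per_trial = 5, seed = 78))
  expect_false(identical(a$subjects, c2$subjects))
})

test_that("noiseless trials reproduce the load template exactly", {
  set.seed(104)
  cfg <- generator_config(n_subjects = 1, speeds = 2.78, steps_per_trial = 3,
                          noise_scale = 0, seed = 9)
  subj <- generate_subject("S", 1, 0)
  tr <- generate_trial(subj, 2.78, cfg)
  st <- tr$steps[1, ]
  idx <- which((seq_along(tr$vgrf) - 1) / tr$grf_rate >= st$t0 &
                 (seq_along(tr$vgrf) - 1) / tr$grf_rate < st$t0 + st$stance_s)
  tau <- ((idx - 1) / tr$grf_rate - st$t0) / st$stance_s
  expected <- ssl_template(tau, st$peak_achilles, st$tau_peak_achilles) *
    tr$body_weight_n
  expect_equal(tr$ssl[idx, "achilles"], expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(generator_config(trial_duration = -1))
  expect_error(generate_trial(subj, -2, cfg))
})

test_that("cadence and stance time decrease with speed", {
  set.seed(105)
  cfg <- generator_config(n_subjects = 1, speeds = c(2.22, 3.33),
                          steps_per_trial = 10, seed = 5)
  subj <- generate_subject("S", 1)
  slow <- generate_trial(subj, 2.22, cfg)
  fast <- generate_trial(subj, 3.33, cfg)
  expect_gt(mean(slow$steps$stride_s), mean(fast$steps$stride_s))
  expect_gt(mean(slow$steps$stance_s), mean(fast$steps$stance_s))
  expect_gt(mean(fast$steps$peak_achilles), mean(slow$steps$peak_achilles))
})

test_that("corruption tagging is binomial at the configured rate", {
  cfg <- generator_config(n_subjects = 5, speeds = c(2.22, 2.78, 3.33),
                          steps_per_trial = 25, corrupt_fraction = 0.1,
                          seed = 42)
  coh <- generate_cohort(cfg)
  tags <- unlist(lapply(coh$trials, function(tr) tr$steps$corrupted))
  n <- length(tags)
  phat <- mean(tags)
  expect_gt(n, 300)
  # within 4 binomial standard errors of 0.1
  expect_lt(abs(phat - 0.1), 4 * sqrt(0.1 * 0.9 / n))
})

test_that("artifact injection is identity at zero corruption and shapes artifacts correctly", {
  cfg0 <- generator_config(n_subjects = 1, speeds = 2.78, steps_per_trial = 6,
                           corrupt_fraction = 0, seed = 3)
  set.seed(3)
  subj <- generate_subject("S", 1)
  tr <- generate_trial(subj, 2.78, cfg0)
  expect_identical(inject_artifacts(tr, cfg0), tr)

  coh <- corrupt_cohort()
  kinds <- unlist(lapply(coh$trials, function(tr) tr$steps$artifact))
  expect_true(all(c("dropout", "inflate", "amplitude") %in% kinds))
  for (id in names(coh$trials)) {
    tr <- coh$trials[[id]]
    for (k in which(tr$steps$corrupted)) {
      st <- tr$steps[k, ]
      if (st$artifact == "dropout") {
        i0 <- round((st$ic_grf - 1) / tr$grf_rate * tr$imu_rate) + 1L + 12L
        expect_true(all(tr$foot$acc[i0:(i0 + 21L), ] == 0))
      } else if (st$artifact == "inflate") {
        seg <- segment_steps_grf(tr$vgrf, tr$grf_rate)
        j <- which.min(abs(seg$ic - st$ic_grf))
        expect_gt((seg$to[j] - seg$ic[j]) / tr$grf_rate, 0.5)
      } else if (st$artifact == "amplitude") {
        idx <- st$ic_grf:(st$to_grf - 1)
        peak_bw <- max(tr$ssl[idx, ]) / tr$body_weight_n
        expect_gt(peak_bw, 15)
      }
    }
  }
})

test_that("quaternion streams stay unit norm after noise injection", {
  coh <- small_cohort()
  for (tr in coh$trials[1:2]) {
    expect_lt(max(abs(sqrt(rowSums(tr$foot$quat^2)) - 1)), 1e-6)
    expect_lt(max(abs(sqrt(rowSums(tr$pelvis$quat^2)) - 1)), 1e-6)
  }
})

test_that("true peak load is predictable from speed and mass", {
  coh <- fixture("learnability_cohort", function()
    generate_cohort(generator_config(n_subjects = 8,
                                     speeds = c(2.22, 2.78, 3.33),
                                     steps_per_trial = 15, seed = 606)))
  df <- do.call(rbind, lapply(coh$trials, function(tr)
    data.frame(peak = tr$steps$peak_achilles, speed = tr$speed,
               mass = coh$subjects$mass_kg[coh$subjects$subject_id == tr$subject_id])))
  fit <- lm(peak ~ speed + mass, data = df)
  expect_gt(summary(fit)$r.squared, 0.5)
})

test_that("dataset round trip is bit-identical and validated", {
  coh <- generate_cohort(generator_config(n_subjects = 2, speeds = 2.78,
                                          steps_per_trial = 4, seed = 12,
                                          corrupt_fraction = 0.2))
  d <- file.path(tempdir(), "cohort_rt")
  unlink(d, recursive = TRUE)
  write_dataset(coh, d)
  back <- read_dataset(d)
  expect_identical(back$subjects$mass_kg, coh$subjects$mass_kg)
  for (id in names(coh$trials)) {
    expect_identical(back$trials[[id]]$vgrf, coh$trials[[id]]$vgrf)
    expect_identical(unname(back$trials[[id]]$foot$acc),
                     unname(coh$trials[[id]]$foot$acc))
    expect_identical(unname(back$trials[[id]]$foot$quat),
                     unname(coh$trials[[id]]$foot$quat))
    expect_identical(unname(back$trials[[id]]$ssl),
                     unname(coh$trials[[id]]$ssl))
    expect_equal(back$trials[[id]]$steps$t0, coh$trials[[id]]$steps$t0)
  }

  # missing trial file names the file
  file.remove(file.path(d, "trials", names(coh$trials)[1], "vgrf.csv"))
  expect_error(read_dataset(d), "vgrf.csv")

  # invariant violations in the subject table are rejected
  d2 <- file.path(tempdir(), "cohort_bad")
  unlink(d2, recursive = TRUE)
  write_dataset(coh, d2)
  subj <- data.table::fread(file.path(d2, "subjects.csv"))
  subj$mass_kg[1] <- -5
  data.table::fwrite(subj, file.path(d2, "subjects.csv"))
  expect_error(read_dataset(d2), "mass")
})
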