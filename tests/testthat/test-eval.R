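test_that("fold plans are balanced, exhaustive and deterministic", {
  ids <- sprintf("S%02d", 1:43)
  plan <- make_folds(ids, 5, seed = 3)
  sizes <- sort(as.vector(table(plan$assignments)), decreasing = TRUE)
  expect_equal(sizes, c(9, 9, 9, 8, 8))
  expect_setequal(names(plan$assignments), ids)
  # every subject tested exactly once
  expect_equal(sum(sizes), 43)
  # validation subjects never overlap their fold's test set
  for (f in 1:5) {
    test_s <- names(plan$assignments)[plan$assignments == f]
    expect_length(intersect(plan$val_subjects[[f]], test_s), 0)
  }
  expect_identical(make_folds(ids, 5, seed = 3), plan)
  expect_false(identical(make_folds(ids, 5, seed = 4)$assignments,
                         plan$assignments))
  expect_error(make_folds(ids[1:3], 5), "fewer subjects")
})

test_that("standardization fits on training data and transfers to other splits", {
  sd1 <- small_steps()
  subjects <- unique(sd1$meta$subject_id)
  train <- subset_steps(sd1, subjects[1:2])
  test <- subset_steps(sd1, subjects[3])
  sc <- fit_scalers(train)
  tr_s <- apply_scalers(train, sc)
  te_s <- apply_scalers(test, sc)
  # training features are z-scored
  expect_lt(max(abs(colMeans(tr_s$F))), 1e-10)
  sds <- apply(tr_s$F, 2, sd)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-6))
  # training channels pooled over timestamps are z-scored
  for (ch in 1:2) {
    expect_lt(abs(mean(tr_s$X[, ch, ])), 1e-10)
    expect_equal(sd(tr_s$X[, ch, ]), 1, tolerance = 1e-3)
  }
  # the test split uses the training statistics, not its own
  expect_gt(max(abs(colMeans(te_s$F))), 1e-6)
  shifted <- test
  shifted$F <- test$F + 5
  sh_s <- apply_scalers(shifted, sc)
  expect_equal(sh_s$F - te_s$F,
               matrix(5 / sc$feature_sd, nrow(te_s$F), ncol(te_s$F),
                      byrow = TRUE), tolerance = 1e-10, ignore_attr = TRUE)
  # zero-variance features are centered, not divided
  degen <- train
  degen$F[, 2] <- 7
  sc2 <- fit_scalers(degen)
  expect_equal(sc2$feature_sd[[2]], 1)
  expect_true(all(apply_scalers(degen, sc2)$F[, 2] == 0))
})

test_that("curve metrics match longhand arithmetic on a toy example", {
  pred <- rbind(c(1, 2, 3, 4), c(2, 2, 2, 2))
  truth <- rbind(c(1, 2, 2, 4), c(1, 3, 2, 2))
  m <- curve_metrics(pred, truth, mape_floor = 0.1)
  expect_equal(unname(m["mse"]), (0 + 0 + 1 + 0 + 1 + 1 + 0 + 0) / 8)
  mape_hand <- 100 * mean(c(0, 0, 1 / 2, 0, 1 / 1, 1 / 3, 0, 0))
  expect_equal(unname(m["mape"]), mape_hand)
  centers <- colMeans(truth)
  sstot <- sum(sweep(truth, 2, centers)^2)
  expect_equal(unname(m["r2"]), 1 - 3 / sstot)

  perfect <- curve_metrics(truth, truth)
  expect_equal(unname(perfect), c(0, 0, 1))

  # predicting the pooled mean curve scores R^2 = 0 by construction
  meanpred <- matrix(centers, 2, 4, byrow = TRUE)
  expect_equal(unname(curve_metrics(meanpred, truth)["r2"]), 0)
  expect_error(curve_metrics(pred, truth[, 1:3]), "mismatch")
})

test_that("the curve MAPE floor excludes near-zero truth values", {
  truth <- matrix(c(0.01, 1, 2, 0.05), 1)
  pred <- truth + 0.5
  m <- curve_metrics(pred, truth)
  expect_equal(unname(m["mape"]), 100 * mean(c(0.5 / 1, 0.5 / 2)))
})

test_that("characteristic metrics match longhand values and vanish on identity", {
  tau <- seq(0, 1, length.out = 100)
  truth <- rbind(ssl_template(tau, 4, 0.5), ssl_template(tau, 5, 0.4))
  stance <- c(0.3, 0.25)
  same <- characteristic_metrics(truth, truth, stance, "achilles")
  expect_true(all(same$metrics$mse == 0))
  expect_true(all(same$metrics$mape == 0))
  expect_equal(same$n_degenerate_lr, 0)

  shifted <- truth + 0.5
  ch <- characteristic_metrics(shifted, truth, stance, "achilles")
  peak_row <- ch$metrics[ch$metrics$characteristic == "peak", ]
  expect_equal(peak_row$mse, 0.25, tolerance = 1e-12)
  imp_row <- ch$metrics[ch$metrics$characteristic == "impulse", ]
  imp_err <- 0.5 * stance   # constant offset integrates to 0.5 BW * stance
  expect_equal(imp_row$mse, mean(imp_err^2), tolerance = 1e-6)
})

test_that("macro-averaged summary equals the unweighted mean of fold metrics", {
  fm <- data.frame(fold = rep(1:3, 2), model = "mean", sensors = "dual",
                   structure = rep(c("achilles", "knee"), each = 3),
                   mse = c(1, 2, 3, 4, 5, 6))
  agg <- stats::aggregate(fm["mse"], fm[c("model", "sensors", "structure")], mean)
  expect_setequal(agg$mse, c(2, 5))
})

test_that("cross-validated evaluation keeps subject sets disjoint and reports all cells", {
  sd1 <- small_steps()
  folds <- make_folds(unique(sd1$meta$subject_id), 3, seed = 5)
  specs <- list(model_spec("mean"), model_spec("linear_l1"))
  rep1 <- evaluate_models(sd1, specs, folds, structures = c("achilles", "knee"))
  expect_equal(nrow(rep1$fold_metrics), 3 * 2 * 2)
  expect_equal(nrow(rep1$summary), 2 * 2)
  expect_true(all(rep1$fold_metrics$r2 <= 1))
  expect_true(all(rep1$fold_metrics$mape >= 0))
  # macro-average property on the real report
  cell <- subset(rep1$fold_metrics, model == "mean" & structure == "knee")
  expect_equal(subset(rep1$summary, model == "mean" & structure == "knee")$mse,
               mean(cell$mse))
  # the linear baseline with amplitude-bearing features beats the mean model
  expect_lt(subset(rep1$summary, model == "linear_l1" & structure == "achilles")$mse,
            subset(rep1$summary, model == "mean" & structure == "achilles")$mse)
})

test_that("channel ablation removes exactly one channel and reports deltas", {
  d <- local({
    set.seed(71)
    n <- 60; T <- 100
    amp <- runif(n, 0.5, 1.5)
    base_curve <- ssl_template(seq(0, 1, length.out = T), 1, 0.5)
    X <- array(0, dim = c(n, 2, T), dimnames = list(NULL, c("signal", "noise"), NULL))
    for (i in 1:n) {
      X[i, 1, ] <- amp[i] * base_curve + rnorm(T, 0, 0.01)
      X[i, 2, ] <- rnorm(T, 0, 1)     # carries no information
    }
    subj <- rep(sprintf("S%d", 1:6), each = 10)
    list(X = X, F = matrix(0, n, 1), Y = list(achilles = outer(3 * amp, base_curve)),
         meta = data.frame(subject_id = subj, stance_duration = 0.3))
  })
  steps <- structure(c(d, list(sensors = "dual")), class = "runload_steps")
  sp <- model_spec("ts_lstm", max_epochs = 25, patience = 25, batch_size = 16,
                   seed = 8)
  res_noise <- ablate_channel(sp, steps, "noise", sprintf("S%d", 1:4), "S5", "S6",
                              structure = "achilles")
  expect_equal(res_noise$channel, "noise")
  # removing a pure-noise channel changes performance only marginally
  expect_lt(abs(res_noise$delta["mse"]), 0.05)
  res_sig <- ablate_channel(sp, steps, "signal", sprintf("S%d", 1:4), "S5", "S6",
                            structure = "achilles")
  # removing the informative channel costs real accuracy
  expect_gt(res_sig$delta["mse"], abs(res_noise$delta["mse"]))
  expect_error(ablate_channel(sp, steps, "absent", sprintf("S%d", 1:4), "S5", "S6"),
               "invalid channel")
})
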