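#' Subject-level fold plan for cross-validation
#'
#' Subjects are shuffled and assigned round-robin to `k` folds (sizes differ
#' by at most one). Within each fold, the non-test subjects are split
#' subject-wise into five-sixths training and one-sixth validation. Train,
#' validation and test subject sets are pairwise disjoint by construction.
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param k Number of folds (default 5).
#' @param seed Seed determining the assignment.
#' @return Object of class `runload_folds`: list with `assignments` (named
#'   fold index per subject) and `val_subjects` (list of validation subject
#'   sets per fold).
#' @export
make_folds <- function(subject_ids, k = 5L, seed = 1L) {
  subject_ids <- unique(subject_ids)
  n <- length(subject_ids)
  if (n < k) stop("fewer subjects than folds")
  rng <- .seeded_rng(seed)
  shuffled <- subject_ids[rng$sample(n)]
  assignments <- stats::setNames(rep(seq_len(k), length.out = n), shuffled)
  val_subjects <- lapply(seq_len(k), function(f) {
    train_pool <- shuffled[assignments[shuffled] != f]
    n_val <- max(1L, round(length(train_pool) / 6))
    sort(train_pool[rng$sample(length(train_pool), n_val)])
  })
  structure(list(k = k, assignments = assignments,
                 val_subjects = val_subjects, seed = seed),
            class = "runload_folds")
}

# local RNG stream independent of the global .Random.seed
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <<- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(sample = function(n, size = n) with_state(function() sample.int(n, size)))
}

#' Split model-ready step data by subject sets
#'
#' @param steps A `runload_steps` object (see [collect_step_data()]).
#' @param subjects Subject identifiers to keep.
#' @return List with `X`, `F`, `Y` (list per structure), `meta` restricted
#'   to steps of the given subjects.
#' @export
subset_steps <- function(steps, subjects) {
  idx <- which(steps$meta$subject_id %in% subjects)
  list(X = steps$X[idx, , , drop = FALSE],
       F = steps$F[idx, , drop = FALSE],
       Y = lapply(steps$Y, function(m) m[idx, , drop = FALSE]),
       meta = steps$meta[idx, , drop = FALSE])
}

#' Fit per-fold standardization scalers
#'
#' Z-scores per tabular feature and per time-series channel (statistics
#' pooled over all training steps and timestamps). Zero-variance columns or
#' channels are centered but not divided.
#'
#' @param train A split as returned by [subset_steps()].
#' @return List of scalers (`feature_mean`, `feature_sd`, `channel_mean`,
#'   `channel_sd`).
#' @export
fit_scalers <- function(train) {
  if (!nrow(train$F) && !dim(train$X)[1]) stop("empty training set")
  fm <- colMeans(train$F)
  fs <- apply(train$F, 2, sd)
  fs[!is.finite(fs) | fs == 0] <- 1
  C <- dim(train$X)[2]
  cm <- vapply(seq_len(C), function(ch) mean(train$X[, ch, ]), numeric(1))
  cs <- vapply(seq_len(C), function(ch) sd(train$X[, ch, ]), numeric(1))
  cs[!is.finite(cs) | cs == 0] <- 1
  list(feature_mean = fm, feature_sd = fs, channel_mean = cm, channel_sd = cs)
}

#' Apply standardization scalers to a split
#'
#' @param split A split as returned by [subset_steps()].
#' @param scalers Scalers fitted on the training split (see [fit_scalers()]).
#' @return The split with standardized `X` and `F`.
#' @export
apply_scalers <- function(split, scalers) {
  split$F <- sweep(sweep(split$F, 2, scalers$feature_mean), 2,
                   scalers$feature_sd, "/")
  for (ch in seq_len(dim(split$X)[2]))
    split$X[, ch, ] <- (split$X[, ch, ] - scalers$channel_mean[ch]) /
      scalers$channel_sd[ch]
  split
}

#' Curve estimation metrics
#'
#' MSE (BW²) pooled over steps and timestamps; MAPE (%) over entries whose
#' true value is at least `mape_floor` BW (the truth approaches zero near
#' initial contact and toe-off, where a naive MAPE diverges); R² pooled with
#' per-timestamp centering of the total sum of squares, so a constant
#' mean-curve prediction scores approximately zero.
#'
#' @param pred,truth n x 100 matrices in BW.
#' @param mape_floor Truth threshold for MAPE inclusion, in BW (default 0.1).
#' @return Named vector: `mse`, `mape`, `r2`.
#' @export
curve_metrics <- function(pred, truth, mape_floor = 0.1) {
  if (!all(dim(pred) == dim(truth))) stop("prediction/truth shape mismatch")
  err <- pred - truth
  mse <- mean(err^2)
  keep <- truth >= mape_floor
  mape <- if (any(keep)) 100 * mean(abs(err[keep]) / truth[keep]) else NA_real_
  centers <- colMeans(truth)
  sstot <- sum(sweep(truth, 2, centers)^2)
  r2 <- if (sstot > 0) 1 - sum(err^2) / sstot else NA_real_
  c(mse = mse, mape = mape, r2 = r2)
}

#' Characteristic estimation metrics
#'
#' Computes peak, impulse and average loading rate from both predicted and
#' true curves with the same stance-phase operations (the predicted curve's
#' own peak frame defines its loading-rate interval) and reports MSE and
#' MAPE per characteristic. Steps with a degenerate loading-rate interval
#' in either curve are dropped from the loading-rate metric and counted.
#'
#' @param pred,truth n x 100 curve matrices in BW.
#' @param stance_durations Stance durations in seconds, length n.
#' @param structure Structure name (selects the loading-rate interval).
#' @return List with `metrics` (data frame: characteristic, mse, mape) and
#'   `n_degenerate_lr`.
#' @export
characteristic_metrics <- function(pred, truth, stance_durations, structure) {
  cfg <- characteristic_config()
  row <- cfg[cfg$structure == structure, ]
  n <- nrow(pred)
  vals <- function(m) {
    t(vapply(seq_len(n), function(i) {
      c(max(m[i, ]),
        ssl_impulse(m[i, ], stance_durations[i]),
        ssl_loading_rate(m[i, ], stance_durations[i], row$p_lower,
                         row$p_upper, row$interval_kind))
    }, numeric(3)))
  }
  vp <- vals(pred)
  vt <- vals(truth)
  ok_lr <- is.finite(vp[, 3]) & is.finite(vt[, 3])
  met <- lapply(1:3, function(j) {
    keep <- if (j == 3) ok_lr else rep(TRUE, n)
    e <- vp[keep, j] - vt[keep, j]
    denom <- abs(vt[keep, j])
    c(mse = mean(e^2), mape = 100 * mean(abs(e) / pmax(denom, 1e-6)))
  })
  list(metrics = data.frame(characteristic = c("peak", "impulse", "loading_rate"),
                            mse = vapply(met, `[`, numeric(1), "mse"),
                            mape = vapply(met, `[`, numeric(1), "mape")),
       n_degenerate_lr = sum(!ok_lr))
}

.inputs_for <- function(split, structure) {
  list(X = split$X, F = split$F, y = split$Y[[structure]])
}

#' Cross-validated model evaluation
#'
#' Runs subject-level k-fold cross-validation for a set of model specs:
#' per-fold standardization (scalers fitted on the training subjects only),
#' training with the nested validation split, prediction on the held-out
#' subjects, and curve plus characteristic metrics. Fold metrics are
#' macro-averaged (unweighted mean over folds).
#'
#' @param steps A `runload_steps` object.
#' @param specs List of [model_spec()] objects.
#' @param folds A [make_folds()] plan covering the step subjects.
#' @param structures Structures to evaluate (default all four).
#' @param keep_models Keep fitted fold models in the result (memory-heavy).
#' @return Object of class `runload_report`: list with `fold_metrics` (one
#'   row per fold x spec x structure), `summary` (macro-averaged), and
#'   optionally `models`.
#' @export
evaluate_models <- function(steps, specs, folds,
                            structures = runload_structures(),
                            keep_models = FALSE) {
  subjects <- unique(steps$meta$subject_id)
  miss <- setdiff(subjects, names(folds$assignments))
  if (length(miss)) stop("fold plan is missing subjects: ",
                         paste(miss, collapse = ", "))
  rows <- list()
  models <- list()
  for (f in seq_len(folds$k)) {
    test_subj <- names(folds$assignments)[folds$assignments == f]
    val_subj <- folds$val_subjects[[f]]
    train_subj <- setdiff(subjects, c(test_subj, val_subj))
    stopifnot(length(intersect(train_subj, val_subj)) == 0,
              length(intersect(train_subj, test_subj)) == 0,
              length(intersect(val_subj, test_subj)) == 0)
    tr <- subset_steps(steps, train_subj)
    va <- subset_steps(steps, val_subj)
    te <- subset_steps(steps, test_subj)
    scalers <- fit_scalers(tr)
    tr <- apply_scalers(tr, scalers)
    va <- apply_scalers(va, scalers)
    te <- apply_scalers(te, scalers)
    for (spec in specs) {
      for (st in structures) {
        sp <- spec
        sp$structure <- st
        fit <- fit_model(sp, .inputs_for(tr, st), .inputs_for(va, st))
        pred <- predict_curves(fit, .inputs_for(te, st))
        truth <- te$Y[[st]]
        cm <- curve_metrics(pred, truth)
        ch <- characteristic_metrics(pred, truth, te$meta$stance_duration, st)
        chm <- ch$metrics
        rows[[length(rows) + 1L]] <- data.frame(
          fold = f, model = sp$model_type, sensors = sp$sensors,
          structure = st, n_test_steps = nrow(truth),
          mse = cm["mse"], mape = cm["mape"], r2 = cm["r2"],
          peak_mse = chm$mse[1], peak_mape = chm$mape[1],
          impulse_mse = chm$mse[2], impulse_mape = chm$mape[2],
          loading_rate_mse = chm$mse[3], loading_rate_mape = chm$mape[3],
          n_degenerate_lr = ch$n_degenerate_lr,
          row.names = NULL)
        if (keep_models)
          models[[paste(f, sp$model_type, st, sep = "_")]] <- fit
      }
    }
  }
  fold_metrics <- do.call(rbind, rows)
  agg_cols <- c("mse", "mape", "r2", "peak_mse", "peak_mape", "impulse_mse",
                "impulse_mape", "loading_rate_mse", "loading_rate_mape")
  summary <- stats::aggregate(fold_metrics[agg_cols],
                              fold_metrics[c("model", "sensors", "structure")],
                              mean)
  structure(list(fold_metrics = fold_metrics, summary = summary,
                 models = if (keep_models) models else NULL),
            class = "runload_report")
}

#' @export
print.runload_report <- function(x, ...) {
  cat("runload cross-validation report (macro-averaged over folds):\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Single-channel ablation of a time-series model
#'
#' Retrains the spec from scratch with one IMU channel removed from the
#' input tensor and reports the held-out metric change against the full
#' model under the same split.
#'
#' @param spec A time-series [model_spec()] (`ts_lstm` or `hybrid_lstm`).
#' @param steps A `runload_steps` object.
#' @param channel Channel index (or name) to omit.
#' @param train_subjects,val_subjects,test_subjects Disjoint subject sets.
#' @param structure Structure to evaluate.
#' @return List with `full` and `ablated` curve metrics, `delta` (ablated -
#'   full) and the omitted channel name.
#' @export
ablate_channel <- function(spec, steps, channel, train_subjects, val_subjects,
                           test_subjects, structure = "achilles") {
  ch_names <- dimnames(steps$X)[[2]]
  if (is.character(channel)) channel <- match(channel, ch_names)
  if (is.na(channel) || channel < 1 || channel > length(ch_names))
    stop("invalid channel index")
  run <- function(drop_ch) {
    s <- steps
    if (!is.null(drop_ch)) s$X <- s$X[, -drop_ch, , drop = FALSE]
    tr <- subset_steps(s, train_subjects)
    va <- subset_steps(s, val_subjects)
    te <- subset_steps(s, test_subjects)
    scalers <- fit_scalers(tr)
    tr <- apply_scalers(tr, scalers)
    va <- apply_scalers(va, scalers)
    te <- apply_scalers(te, scalers)
    sp <- spec
    sp$structure <- structure
    fit <- fit_model(sp, .inputs_for(tr, structure), .inputs_for(va, structure))
    curve_metrics(predict_curves(fit, .inputs_for(te, structure)),
                  te$Y[[structure]])
  }
  full <- run(NULL)
  ablated <- run(channel)
  list(channel = ch_names[channel], full = full, ablated = ablated,
       delta = ablated - full)
}
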