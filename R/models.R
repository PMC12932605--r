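.model_types <- c("hybrid_lstm", "ts_lstm", "f_nn", "linear_l1", "mean")
.arch_code <- c(hybrid_lstm = 1L, ts_lstm = 0L, f_nn = 2L)

#' Model specification
#'
#' Default hyperparameters: two bidirectional LSTM layers with
#' 20 units each, dense layer of 20 ReLU neurons, dropout 0.2, Adam with
#' initial learning rate 1e-4 decayed by 0.90 every 10,000 optimizer steps,
#' batch size 64, at most 500 epochs with early-stopping patience 30. One
#' model is trained per musculoskeletal structure; every model emits a
#' 100-sample stance-phase load curve.
#'
#' @param model_type One of `"hybrid_lstm"`, `"ts_lstm"`, `"f_nn"`,
#'   `"linear_l1"`, `"mean"`.
#' @param sensors `"dual"`, `"pelvis"` or `"foot"`.
#' @param structure One of the four structure names.
#' @param recurrent_units,dense_units,dropout,learning_rate,decay,decay_steps,batch_size,max_epochs,patience
#'   Training hyperparameters (see defaults).
#' @param lambda_grid L1 penalty grid for `"linear_l1"` (7-point log grid
#'   spanning the tuning range 1e-4 to 100).
#' @param recurrent_pool How the second bidirectional layer feeds the dense
#'   head: `"mean"` (default) averages the output sequence over the 100
#'   timestamps; `"final"` concatenates the two directions' final hidden
#'   states. The sequence summary is not specified by the architecture
#'   description; averaging shortens the gradient path through time and
#'   trains markedly faster at equal capacity.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return Object of class `runload_model_spec`.
#' @export
model_spec <- function(model_type = "hybrid_lstm",
                       sensors = "dual",
                       structure = "achilles",
                       recurrent_units = 20L,
                       dense_units = 20L,
                       dropout = 0.2,
                       learning_rate = 1e-4,
                       decay = 0.90,
                       decay_steps = 10000L,
                       batch_size = 64L,
                       max_epochs = 500L,
                       patience = 30L,
                       lambda_grid = 10^seq(-4, 2),
                       recurrent_pool = c("mean", "final"),
                       seed = 1L) {
  recurrent_pool <- match.arg(recurrent_pool)
  model_type <- match.arg(model_type, .model_types)
  sensors <- match.arg(sensors, c("dual", "pelvis", "foot"))
  structure <- match.arg(structure, .structures)
  stopifnot(all(lambda_grid >= 1e-4 - 1e-12), all(lambda_grid <= 100 + 1e-9),
            length(lambda_grid) >= 1)
  structure(list(model_type = model_type, sensors = sensors,
                 structure = structure, recurrent_units = recurrent_units,
                 dense_units = dense_units, dropout = dropout,
                 learning_rate = learning_rate, decay = decay,
                 decay_steps = as.integer(decay_steps),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lambda_grid = lambda_grid,
                 recurrent_pool = recurrent_pool,
                 seed = as.integer(seed)),
            class = "runload_model_spec")
}

# n x C x 100 array -> armadillo-cube layout used by the C++ engine
.pool_code <- function(spec) {
  if (identical(spec$recurrent_pool, "final")) 0L else 1L
}

.as_cube <- function(X) {
  if (is.null(X)) array(0, dim = c(1, 1, 1)) else X
}

.null_mat <- function(n) matrix(0, n, 0)

#' Fit one load-estimation model
#'
#' Dispatches on the spec's model type. The recurrent and feed-forward
#' networks train with Adam (MSE loss) and early stopping on the validation
#' loss, restoring the best-epoch weights; their output-layer bias is
#' initialized to the training-mean curve. The L1 linear baseline fits one
#' lasso path per output timestamp with `glmnet` and selects the penalty
#' from the spec's grid by validation MSE. The mean regressor stores the
#' pointwise training-mean curve and uses no validation set.
#'
#' @param spec A [model_spec()].
#' @param train,val Lists with elements `X` (n x channels x 100 array,
#'   standardized), `F` (n x features matrix, standardized) and `y`
#'   (n x 100 target curves in BW). `val` is ignored by the mean regressor.
#' @return Object of class `runload_model`.
#' @export
fit_model <- function(spec, train, val = NULL) {
  n <- nrow(train$y)
  if (is.null(n) || n == 0) stop("empty training set")
  mean_curve <- colMeans(train$y)
  fitted <- switch(spec$model_type,
    mean = list(mean_curve = mean_curve),
    linear_l1 = .fit_linear_l1(spec, train, val),
    {
      if (is.null(val)) stop("validation set required for network training")
      arch <- .arch_code[[spec$model_type]]
      C <- if (arch == 2L) 1L else dim(train$X)[2]
      d <- if (arch == 0L) 0L else ncol(train$F)
      params0 <- cpp_init_params(arch, C, d, spec$recurrent_units,
                                 spec$dense_units, ncol(train$y),
                                 mean_curve, spec$seed)
      hp <- list(learning_rate = spec$learning_rate, decay = spec$decay,
                 decay_steps = spec$decay_steps, batch_size = spec$batch_size,
                 max_epochs = spec$max_epochs, patience = spec$patience,
                 dropout = spec$dropout, seed = spec$seed,
                 pool = if (identical(spec$recurrent_pool, "final")) 0L else 1L)
      res <- cpp_train(arch, .as_cube(train$X),
                       if (d > 0) train$F else .null_mat(n), train$y,
                       .as_cube(val$X),
                       if (d > 0) val$F else .null_mat(nrow(val$y)), val$y,
                       params0, hp)
      list(params = res$params,
           history = list(train = res$history_train, val = res$history_val),
           best_epoch = res$best_epoch, n_epochs = res$n_epochs,
           best_val = res$best_val, arch = arch)
    })
  structure(list(spec = spec, fitted = fitted), class = "runload_model")
}

.fit_linear_l1 <- function(spec, train, val) {
  if (is.null(val)) stop("validation set required for lambda selection")
  lambda <- sort(spec$lambda_grid, decreasing = TRUE)
  n_out <- ncol(train$y)
  fits <- lapply(seq_len(n_out), function(j)
    glmnet::glmnet(train$F, train$y[, j], alpha = 1, lambda = lambda,
                   family = "gaussian"))
  val_mse <- sapply(seq_along(lambda), function(li) {
    pred <- sapply(fits, function(f) predict(f, val$F, s = lambda[li]))
    mean((pred - val$y)^2)
  })
  best <- which.min(val_mse)
  coefs <- sapply(fits, function(f) as.numeric(predict(f, type = "coefficients",
                                                       s = lambda[best])))
  list(intercept = coefs[1, ], weights = coefs[-1, , drop = FALSE],
       lambda = lambda[best], lambda_grid = lambda, val_mse = val_mse)
}

#' Predict stance-phase load curves
#'
#' Every model type shares this contract: one 100-value curve per step,
#' clipped at zero (loads are non-negative).
#'
#' @param model A fitted `runload_model`.
#' @param data List with `X` and/or `F` as required by the model type,
#'   standardized with the training scalers.
#' @return n x 100 matrix of predicted curves in BW.
#' @export
predict_curves <- function(model, data) {
  spec <- model$spec
  n <- if (!is.null(data$F)) nrow(data$F) else dim(data$X)[1]
  pred <- switch(spec$model_type,
    mean = matrix(model$fitted$mean_curve, n, length(model$fitted$mean_curve),
                  byrow = TRUE),
    linear_l1 = sweep(data$F %*% model$fitted$weights, 2,
                      model$fitted$intercept, "+"),
    {
      arch <- model$fitted$arch
      d <- if (arch == 0L) 0L else ncol(data$F)
      out <- cpp_predict(arch, model$fitted$params, .as_cube(data$X),
                         if (d > 0) data$F else .null_mat(n),
                         0, 1L, spec$seed, .pool_code(spec))
      out[, , 1]
    })
  pred[pred < 0] <- 0
  pred
}

#' Monte Carlo dropout uncertainty for one model
#'
#' Performs repeated stochastic forward passes with the dropout layers
#' active at inference, and summarizes the spread: the per-timestamp
#' standard deviation of the predicted curve and the standard deviation of
#' each derived characteristic (peak, impulse, loading rate) computed from
#' every pass. Models without dropout layers (mean, linear) are an error.
#'
#' @param model A fitted network `runload_model` (hybrid, TS or F-NN).
#' @param data Standardized inputs as in [predict_curves()].
#' @param stance_durations Stance durations in seconds (for characteristics).
#' @param n_passes Number of stochastic passes (default 100).
#' @param seed Seed for the dropout masks.
#' @param dropout Dropout rate at inference; defaults to the spec's rate.
#' @return List with `mean_curve` (n x 100), `sd_curve` (n x 100),
#'   `sd_characteristics` (n x 3: peak, impulse, loading rate) and
#'   `n_passes`.
#' @export
mc_dropout <- function(model, data, stance_durations, n_passes = 100L,
                       seed = 1L, dropout = NULL) {
  spec <- model$spec
  if (!spec$model_type %in% c("hybrid_lstm", "ts_lstm", "f_nn"))
    stop("Monte Carlo dropout requires a model with dropout layers")
  if (is.null(dropout)) dropout <- spec$dropout
  arch <- model$fitted$arch
  n <- if (!is.null(data$F)) nrow(data$F) else dim(data$X)[1]
  d <- if (arch == 0L) 0L else ncol(data$F)
  passes <- cpp_predict(arch, model$fitted$params, .as_cube(data$X),
                        if (d > 0) data$F else .null_mat(n),
                        dropout, as.integer(n_passes), as.integer(seed),
                        .pool_code(spec))
  passes[passes < 0] <- 0
  nP <- dim(passes)[3]
  mean_curve <- apply(passes, c(1, 2), mean)
  sd_curve <- apply(passes, c(1, 2), sd)
  cfg <- characteristic_config()
  row <- cfg[cfg$structure == spec$structure, ]
  chars <- array(NA_real_, dim = c(n, 3, nP))
  for (k in seq_len(nP)) {
    for (i in seq_len(n)) {
      curve <- passes[i, , k]
      chars[i, 1, k] <- max(curve)
      chars[i, 2, k] <- ssl_impulse(curve, stance_durations[i])
      chars[i, 3, k] <- ssl_loading_rate(curve, stance_durations[i],
                                         row$p_lower, row$p_upper,
                                         row$interval_kind)
    }
  }
  sd_chars <- apply(chars, c(1, 2), function(v) sd(v[is.finite(v)]))
  colnames(sd_chars) <- c("peak", "impulse", "loading_rate")
  list(mean_curve = mean_curve, sd_curve = sd_curve,
       sd_characteristics = sd_chars, n_passes = nP)
}

#' @export
print.runload_model <- function(x, ...) {
  cat(sprintf("runload model: %s (%s sensors, %s)\n", x$spec$model_type,
              x$spec$sensors, x$spec$structure))
  if (!is.null(x$fitted$best_epoch))
    cat(sprintf("  trained %d epochs, best epoch %d, best val MSE %.4g\n",
                x$fitted$n_epochs, x$fitted$best_epoch, x$fitted$best_val))
  invisible(x)
}
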