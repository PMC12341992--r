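#' Training control parameters for ReLU network regression
#'
#' Bundles the optimization protocol. The epoch count, batch count and
#' dropout rate follow the simulation protocol the test was studied under
#' (200 epochs, 20 mini-batches per epoch, dropout 0.05); the optimizer,
#' learning rate, restart count and initialization scale are tuning knobs
#' of this implementation.
#'
#' The batch size is derived as `ceiling(n / num_batches)` so that exactly
#' `num_batches` batches cover the data each epoch (the last batch may be
#' smaller). `learning_rate = NULL` selects a depth-aware default: 0.03 for
#' a single hidden layer, 0.01 for deeper networks — deep stacks need
#' smaller steps to train stably under Adam. `n_restarts` controls
#' multistart optimization: the network is trained from `n_restarts`
#' independent seeded initializations and the fit with the smallest
#' in-sample mean squared error (dropout disabled) is kept. Multistart is
#' what makes the fitted function replicate-stable on hard, multimodal
#' landscapes (e.g. high-frequency signals), which the calibration of the
#' goodness-of-fit test depends on.
#'
#' @param epochs Number of passes over the training data (default 200).
#' @param num_batches Number of mini-batches per epoch (default 20).
#' @param learning_rate Step size, or `NULL` for the depth-aware default.
#' @param optimizer `"adam"` (default) or `"sgd"` (plain / heavy-ball).
#' @param momentum Heavy-ball momentum for `optimizer = "sgd"`; 0 gives
#'   plain stochastic gradient descent. Ignored by Adam.
#' @param dropout Dropout rate applied to each hidden unit during training
#'   (default 0.05); disabled at evaluation.
#' @param n_restarts Number of seeded restarts for multistart training
#'   (default 10).
#' @param init_scale Multiplier on the fan-in-scaled uniform initialization
#'   bound of the first hidden layer (default 1).
#' @param seed Integer seed controlling initialization, batch shuffling and
#'   dropout masks; the fit is fully reproducible given the seed.
#' @return An object of class `"relu_control"`.
#' @export
relu_control <- function(epochs = 200L, num_batches = 20L,
                         learning_rate = NULL,
                         optimizer = c("adam", "sgd"), momentum = 0,
                         dropout = 0.05, n_restarts = 10L, init_scale = 1,
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  epochs <- as.integer(epochs)
  num_batches <- as.integer(num_batches)
  n_restarts <- as.integer(n_restarts)
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  if (num_batches < 1L) stop("`num_batches` must be >= 1", call. = FALSE)
  if (n_restarts < 1L) stop("`n_restarts` must be >= 1", call. = FALSE)
  if (!is.null(learning_rate) &&
      (!is.numeric(learning_rate) || learning_rate <= 0))
    stop("`learning_rate` must be positive (or NULL for the default)",
         call. = FALSE)
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1)
    stop("`dropout` must be in [0, 1)", call. = FALSE)
  structure(
    list(epochs = epochs, num_batches = num_batches,
         learning_rate = learning_rate, optimizer = optimizer,
         momentum = momentum, dropout = dropout, n_restarts = n_restarts,
         init_scale = init_scale, seed = as.integer(seed)),
    class = "relu_control"
  )
}

default_lr <- function(n_hidden_layers) if (n_hidden_layers > 1L) 0.01 else 0.03

#' Fit a ReLU network regression
#'
#' Trains a feed-forward ReLU network (see [relu_spec()]) on a numeric
#' covariate matrix by mini-batch gradient descent on the mean squared
#' error, with dropout on every hidden unit during training. The returned
#' object supports `predict()`, `fitted()`, `residuals()`, `coef()` (the
#' flattened parameter vector), `summary()` and `plot()` (loss trace).
#'
#' @param x Numeric matrix of covariates, samples in rows.
#' @param y Numeric response vector, `length(y) == nrow(x)`.
#' @param spec A [relu_spec()]; if `NULL`, built from `kind` and `nrow(x)`
#'   via [build_architecture()].
#' @param kind Architecture rule used when `spec` is `NULL`.
#' @param control A [relu_control()] object.
#' @return An object of class `"relu_net"`.
#' @examples
#' d <- gen_sim1(300, "quadratic", seed = 1)
#' fit <- relu_net(d$x, d$y, kind = "shallow",
#'                 control = relu_control(n_restarts = 2, seed = 1))
#' mean(residuals(fit)^2)
#' @export
relu_net <- function(x, y, spec = NULL,
                     kind = c("shallow", "deep1", "deep2"),
                     control = relu_control()) {
  x <- as.matrix(x)
  if (!is.numeric(x) || !is.numeric(y))
    stop("`x` and `y` must be numeric", call. = FALSE)
  if (nrow(x) != length(y))
    stop("rows(x) must equal length(y)", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in `x` or `y`", call. = FALSE)
  if (is.null(spec))
    spec <- build_architecture(match.arg(kind), n = nrow(x),
                               input_dim = ncol(x),
                               dropout_rate = control$dropout)
  stopifnot(inherits(spec, "relu_spec"), inherits(control, "relu_control"))
  if (spec$input_dim != ncol(x))
    stop("spec input_dim (", spec$input_dim, ") != ncol(x) (", ncol(x), ")",
         call. = FALSE)
  if (nrow(x) < control$num_batches)
    stop("need at least `num_batches` rows to train", call. = FALSE)

  lr <- control$learning_rate %||% default_lr(length(spec$hidden_widths))
  use_adam <- as.integer(control$optimizer == "adam")

  best <- NULL
  best_mse <- Inf
  for (k in seq_len(control$n_restarts)) {
    seed_k <- restart_seed(control$seed, k)
    fit <- cpp_relu_train(x, y, spec$hidden_widths, control$epochs,
                          control$num_batches, lr, control$dropout,
                          control$momentum, use_adam, control$init_scale,
                          seed_k)
    pred <- drop(cpp_relu_predict(fit$weights, fit$biases, x))
    mse <- mean((y - pred)^2)
    if (mse < best_mse) {
      best_mse <- mse
      best <- fit
      best$restart <- k
      best$fitted <- pred
    }
  }

  structure(
    list(spec = spec, weights = best$weights, biases = best$biases,
         epoch_loss = as.numeric(best$epoch_loss),
         fitted.values = best$fitted, y = y,
         train_mse = best_mse, restart_used = best$restart,
         learning_rate = lr, control = control, call = match.call()),
    class = "relu_net"
  )
}

# deterministic restart seeds, kept inside 32-bit integer range
restart_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7777 * (k - 1)) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict from a fitted ReLU network
#'
#' Evaluation-mode forward map: dropout disabled, deterministic given the
#' trained parameters.
#'
#' @param object A fitted `"relu_net"`.
#' @param newx Covariate matrix with `ncol(newx) == spec$input_dim`.
#' @param ... Unused.
#' @return Numeric vector of fitted values, one per row of `newx`.
#' @export
predict.relu_net <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (ncol(newx) != object$spec$input_dim)
    stop("ncol(newx) (", ncol(newx), ") != network input_dim (",
         object$spec$input_dim, ")", call. = FALSE)
  drop(cpp_relu_predict(object$weights, object$biases, newx))
}

#' @export
fitted.relu_net <- function(object, ...) object$fitted.values

#' @export
residuals.relu_net <- function(object, ...) object$y - object$fitted.values

#' @export
coef.relu_net <- function(object, ...) {
  unlist(lapply(seq_along(object$weights), function(l)
    c(as.numeric(object$weights[[l]]), as.numeric(object$biases[[l]]))))
}

#' @export
print.relu_net <- function(x, ...) {
  cat("Fitted ReLU network regression\n")
  print(x$spec)
  cat(sprintf("  in-sample MSE: %.4f  (restart %d of %d, lr %.3g, %s)\n",
              x$train_mse, x$restart_used, x$control$n_restarts,
              x$learning_rate, x$control$optimizer))
  invisible(x)
}

#' @export
summary.relu_net <- function(object, ...) {
  out <- list(
    spec = object$spec,
    n = length(object$y),
    n_parameters = count_parameters(object$spec),
    train_mse = object$train_mse,
    first_epoch_loss = object$epoch_loss[1L],
    final_epoch_loss = object$epoch_loss[length(object$epoch_loss)],
    growth_ratio = growth_condition_ratio(object$spec, length(object$y))
  )
  class(out) <- "summary.relu_net"
  out
}

#' @export
print.summary.relu_net <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  n = %d, parameters = %d, growth ratio = %.3f\n",
              x$n, x$n_parameters, x$growth_ratio))
  cat(sprintf("  epoch loss: %.4f (first) -> %.4f (final); in-sample MSE %.4f\n",
              x$first_epoch_loss, x$final_epoch_loss, x$train_mse))
  invisible(x)
}

#' @export
plot.relu_net <- function(x, ...) {
  graphics::plot(seq_along(x$epoch_loss), x$epoch_loss, type = "l",
                 xlab = "epoch", ylab = "mean minibatch loss",
                 main = "Training loss", ...)
  invisible(x)
}
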