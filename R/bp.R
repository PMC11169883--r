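# --- flat parameter packing for the 3-5-1 style network ------------------
# order: W1 (hidden x m, column-major), b1, W2 (1 x hidden), b2

bp_n_params <- function(m, hidden) hidden * m + hidden + hidden + 1L

bp_unpack <- function(theta, m, hidden) {
  stopifnot(length(theta) == bp_n_params(m, hidden))
  i <- hidden * m
  W1 <- matrix(theta[seq_len(i)], nrow = hidden)
  b1 <- theta[i + seq_len(hidden)]
  W2 <- theta[i + hidden + seq_len(hidden)]
  b2 <- theta[i + 2L * hidden + 1L]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

bp_pack <- function(p) c(as.vector(p$W1), p$b1, p$W2, p$b2)

bp_forward <- function(p, Xs) {
  A1 <- sigmoid(Xs %*% t(p$W1) + matrix(p$b1, nrow(Xs), length(p$b1),
                                        byrow = TRUE))
  list(A1 = A1, yhat = drop(A1 %*% p$W2 + p$b2))
}

# mean-squared-error loss and its exact gradient (chain rule, batch form)
bp_loss_grad <- function(theta, Xs, ys, m, hidden) {
  p <- bp_unpack(theta, m, hidden)
  fw <- bp_forward(p, Xs)
  resid <- fw$yhat - ys
  n <- length(ys)
  loss <- mean(resid^2)
  r <- 2 * resid / n
  gW2 <- drop(crossprod(fw$A1, r))            # dL/dW2, length hidden
  gb2 <- sum(r)
  dZ1 <- (r %*% t(p$W2)) * fw$A1 * (1 - fw$A1)  # n x hidden
  gW1 <- crossprod(dZ1, Xs)                   # hidden x m, matches W1 layout
  gb1 <- colSums(dZ1)
  list(loss = loss, grad = c(as.vector(gW1), gb1, gW2, gb2))
}

#' Fit a back-propagation neural network regressor
#'
#' Feed-forward network (default topology 3-5-1: three inputs, five sigmoid
#' hidden nodes, one linear output) trained by full-batch gradient descent
#' on the mean squared error. Features are standardised and the target is
#' min-max scaled to `[0, 1]` internally for numerical conditioning
#' (training statistics only, frozen for prediction). The stopping
#' criterion `target_error` applies to the training MSE on the original
#' target scale (squared percent moisture): training halts when that MSE
#' drops to `target_error` (default 0.01) or after `max_epochs` epochs.
#'
#' @param X Numeric feature matrix (n x m).
#' @param y Numeric response vector.
#' @param hidden Number of hidden nodes (default 5, from the empirical
#'   hidden-node rule [hidden_nodes_rule()] with a = 3).
#' @param learning_rate Gradient-descent step size (default 0.5 on the
#'   scaled problem; the value is not part of the published protocol).
#' @param max_epochs Maximum number of epochs; 0 returns the initial
#'   weights untouched.
#' @param target_error Stopping MSE on the original target scale
#'   (default 0.01).
#' @param init_weights Optional flat initial parameter vector of length
#'   `hidden*m + hidden + hidden + 1` (26 for the default 3-5-1 topology),
#'   e.g. a metaheuristic-optimised starting point; drawn uniformly in
#'   `[-1, 1]` when `NULL`.
#' @return An object of class `bp_model` with fields `params` (list
#'   `W1,b1,W2,b2`), `init` (the flat initial vector), `epochs`,
#'   `converged`, `mse` (final training MSE, original scale) and `fitted`.
#' @examples
#' set.seed(1)
#' X <- matrix(runif(90), ncol = 3)
#' y <- 10 + 4 * X[, 1] - 2 * X[, 3]
#' m <- bp_fit(X, y, max_epochs = 2000)
#' m$converged
#' @export
bp_fit <- function(X, y, hidden = 5L, learning_rate = 0.5,
                   max_epochs = 5000L, target_error = 0.01,
                   init_weights = NULL) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), max_epochs >= 0L, learning_rate > 0,
            target_error >= 0)
  m <- ncol(X)
  hidden <- as.integer(hidden)
  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)
  y_min <- min(y); y_max <- max(y)
  y_span <- if (y_max > y_min) y_max - y_min else 1
  ys <- (y - y_min) / y_span

  theta <- if (is.null(init_weights)) {
    stats::runif(bp_n_params(m, hidden), -1, 1)
  } else {
    as.numeric(init_weights)
  }
  stopifnot(length(theta) == bp_n_params(m, hidden))
  init <- theta

  orig_mse <- function(th) bp_loss_grad(th, Xs, ys, m, hidden)$loss * y_span^2
  mse <- orig_mse(theta)
  epochs <- 0L
  converged <- mse <= target_error
  while (!converged && epochs < max_epochs) {
    lg <- bp_loss_grad(theta, Xs, ys, m, hidden)
    if (!is.finite(lg$loss)) {
      stop(sprintf("non-finite training loss at epoch %d", epochs),
           call. = FALSE)
    }
    theta <- theta - learning_rate * lg$grad
    epochs <- epochs + 1L
    mse <- orig_mse(theta)
    converged <- mse <= target_error
  }

  params <- bp_unpack(theta, m, hidden)
  fitted_scaled <- bp_forward(params, Xs)$yhat
  structure(
    list(params = params, init = init, hidden = hidden, m = m,
         std = std, y_min = y_min, y_span = y_span,
         learning_rate = learning_rate, target_error = target_error,
         epochs = epochs, converged = converged, mse = mse,
         fitted = fitted_scaled * y_span + y_min),
    class = "bp_model"
  )
}

#' Predict from a fitted BP network
#'
#' @param object A [bp_fit()] model.
#' @param newdata Feature matrix with the same columns as at fit time.
#' @param ... Unused.
#' @return Predicted response vector on the original target scale.
#' @export
predict.bp_model <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  Xs <- standardize_apply(X, object$std)
  bp_forward(object$params, Xs)$yhat * object$y_span + object$y_min
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf(
    "BP regressor %d-%d-1: %d epochs, training MSE %.4g (%s)\n",
    x$m, x$hidden, x$epochs, x$mse,
    if (x$converged) "converged" else "epoch limit"))
  invisible(x)
}
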