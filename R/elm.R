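sigmoid <- function(z) 1 / (1 + exp(-z))

standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1  # constant columns pass through
  list(center = center, scale = scale)
}

standardize_apply <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

as_feature_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  X
}

#' Fit an extreme learning machine regressor
#'
#' Single-hidden-layer network with random (or supplied) input weights and
#' biases and a sigmoid hidden layer; the output weights `beta` are the
#' minimum-norm least-squares solution of `H beta = y`, where `H` is the
#' hidden-layer activation matrix — no iterative training. Features are
#' standardised internally (training statistics only, frozen for
#' prediction).
#'
#' With many hidden units over few inputs the columns of `H` are severely
#' collinear, so the pseudo-inverse is computed with a relative
#' singular-value cutoff `svd_tol`: directions below `svd_tol` times the
#' largest singular value amplify response noise by more than `1/svd_tol`
#' and are discarded. The default 1e-4 keeps the output weights bounded
#' without limiting fit quality on smooth targets.
#'
#' @param X Numeric feature matrix (n x p).
#' @param y Numeric response vector (moisture content in percent).
#' @param hidden_count Number of hidden neurons (default 100).
#' @param input_weights Optional `hidden_count x p` weight matrix; drawn
#'   uniformly in `[-1, 1]` from the global RNG when `NULL`.
#' @param hidden_biases Optional length-`hidden_count` bias vector; same
#'   default draw.
#' @param svd_tol Relative singular-value cutoff of the pseudo-inverse.
#' @return An object of class `elm_model` with the learned output weights
#'   and frozen standardisation parameters.
#' @examples
#' set.seed(1)
#' X <- matrix(runif(60), ncol = 3)
#' y <- 2 * X[, 1] - X[, 2] + 5
#' m <- elm_fit(X, y, hidden_count = 10)
#' rmse(y, predict(m, X))
#' @export
elm_fit <- function(X, y, hidden_count = 100L,
                    input_weights = NULL, hidden_biases = NULL,
                    svd_tol = 1e-4) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) >= 1L, nrow(X) == length(y))
  hidden_count <- as.integer(hidden_count)
  p <- ncol(X)
  if (is.null(input_weights)) {
    input_weights <- matrix(stats::runif(hidden_count * p, -1, 1),
                            nrow = hidden_count)
  }
  if (is.null(hidden_biases)) {
    hidden_biases <- stats::runif(hidden_count, -1, 1)
  }
  stopifnot(identical(dim(input_weights), c(hidden_count, p)),
            length(hidden_biases) == hidden_count)
  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)
  H <- elm_hidden(Xs, input_weights, hidden_biases)
  if (all(apply(H, 2, stats::sd) < 1e-12)) {
    warning("degenerate hidden layer: all activations constant", call. = FALSE)
  }
  beta <- drop(MASS::ginv(H, tol = svd_tol) %*% y)  # truncated min-norm LS
  structure(
    list(hidden_count = hidden_count, input_weights = input_weights,
         hidden_biases = hidden_biases, output_weights = beta,
         std = std, fitted = drop(H %*% beta)),
    class = "elm_model"
  )
}

elm_hidden <- function(Xs, W, b) {
  sigmoid(Xs %*% t(W) + matrix(b, nrow(Xs), length(b), byrow = TRUE))
}

#' Predict from a fitted ELM
#'
#' @param object An [elm_fit()] model.
#' @param newdata Feature matrix with the same columns as at fit time.
#' @param ... Unused.
#' @return Predicted response vector.
#' @export
predict.elm_model <- function(object, newdata, ...) {
  if (is.null(object$output_weights)) stop("model is not fitted", call. = FALSE)
  X <- as_feature_matrix(newdata)
  Xs <- standardize_apply(X, object$std)
  drop(elm_hidden(Xs, object$input_weights, object$hidden_biases) %*%
         object$output_weights)
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("ELM regressor: %d inputs -> %d sigmoid hidden units -> 1\n",
              ncol(x$input_weights), x$hidden_count))
  invisible(x)
}
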