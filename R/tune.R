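#' Empirical hidden-node count rule
#'
#' The usual single-hidden-layer sizing heuristic
#' `h = round(sqrt(m + n)) + a` for `m` input nodes, `n` output nodes and an
#' integer adjustment `a` between 1 and 10. With three inputs, one output
#' and `a = 3` it gives the 5 hidden nodes of the default BP topology.
#'
#' @param m Number of input nodes (>= 1).
#' @param n Number of output nodes (>= 1).
#' @param a Integer adjustment constant in `[1, 10]`.
#' @return Integer hidden-node count.
#' @examples
#' hidden_nodes_rule(3, 1, 3)  # 5
#' @export
hidden_nodes_rule <- function(m, n, a) {
  stopifnot(m >= 1, n >= 1, a >= 1, a <= 10)
  as.integer(round(sqrt(m + n)) + a)
}

#' Tune an ELM or BP regressor with (LC)SSA
#'
#' Wraps the sparrow search optimizer around the two regressors, following
#' standard metaheuristic-neural-network practice:
#' \itemize{
#'   \item `"elm"`: the search space is the flattened hidden-layer random
#'     parameters (input weights plus biases, `hidden_count * p +
#'     hidden_count` dimensions, 400 for 100 hidden nodes on 3 features) in
#'     `[-1, 1]`; the fitness of a candidate is the training RMSE with
#'     output weights re-solved by least squares, and the returned model
#'     re-fits the minimum-norm solution at the optimum.
#'   \item `"bp"`: the search space is the flat initial weight/bias vector
#'     (26 dimensions for the 3-5-1 topology) in `[-1, 1]`; the fitness of a
#'     candidate is the training RMSE of the untrained network with those
#'     weights, and gradient-descent training then fine-tunes from the
#'     optimised initialisation.
#' }
#' Uniform initialisation of the sparrow population gives the SSA-tuned
#' variant, logistic chaotic initialisation the LCSSA-tuned variant.
#'
#' @param model_kind `"elm"` or `"bp"`.
#' @param X Numeric feature matrix.
#' @param y Numeric response vector.
#' @param init_mode `"uniform"` (SSA) or `"logistic"` (LCSSA).
#' @param pop_size,max_iters Sparrow population size and iteration budget
#'   (both default 20, the published training protocol).
#' @param hidden_count ELM hidden-layer size (default 100).
#' @param hidden BP hidden-layer size (default 5).
#' @param svd_tol Relative singular-value cutoff of the ELM least-squares
#'   solve (see [elm_fit()]); used identically inside the fitness and in
#'   the final refit.
#' @param seed Optional integer seed for full reproducibility.
#' @param ... Further arguments passed to [bp_fit()] (e.g.
#'   `learning_rate`, `max_epochs`).
#' @return An object of class `trained_predictor`: list with `kind` (one of
#'   `"SSA-ELM"`, `"LCSSA-ELM"`, `"SSA-BP"`, `"LCSSA-BP"`), the fitted
#'   `model`, and `tuning` (the `ssa_result`, including the fitness trace).
#' @examples
#' set.seed(1)
#' X <- matrix(runif(90), ncol = 3)
#' y <- 20 * X[, 3] + 5
#' tp <- ssa_tune("elm", X, y, hidden_count = 10, pop_size = 6,
#'                max_iters = 3, seed = 1)
#' rmse(y, predict(tp, X))
#' @export
ssa_tune <- function(model_kind = c("elm", "bp"), X, y,
                     init_mode = c("uniform", "logistic"),
                     pop_size = 20L, max_iters = 20L,
                     hidden_count = 100L, hidden = 5L, svd_tol = 1e-4,
                     seed = NULL, ...) {
  model_kind <- match.arg(model_kind)
  init_mode <- match.arg(init_mode)
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  p <- ncol(X)
  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)

  if (model_kind == "elm") {
    hidden_count <- as.integer(hidden_count)
    dims <- hidden_count * p + hidden_count
    objective <- function(theta) {
      W <- matrix(theta[seq_len(hidden_count * p)], nrow = hidden_count)
      b <- theta[hidden_count * p + seq_len(hidden_count)]
      H <- elm_hidden(Xs, W, b)
      # the deployed model uses the truncated min-norm solve, so the
      # fitness must too
      fit <- tryCatch(drop(H %*% (MASS::ginv(H, tol = svd_tol) %*% y)),
                      error = function(e) NULL)
      if (is.null(fit)) return(Inf)
      rmse(y, fit)
    }
  } else {
    hidden <- as.integer(hidden)
    dims <- bp_n_params(p, hidden)
    y_min <- min(y); y_span <- max(y) - y_min
    if (y_span <= 0) y_span <- 1
    ys <- (y - y_min) / y_span
    objective <- function(theta) {
      fw <- bp_forward(bp_unpack(theta, p, hidden), Xs)
      rmse(ys, fw$yhat)
    }
  }

  cfg <- ssa_config(dims = dims, lower = -1, upper = 1, pop_size = pop_size,
                    max_iters = max_iters, init_mode = init_mode, seed = seed)
  res <- ssa_optimize(objective, cfg)

  model <- if (model_kind == "elm") {
    theta <- res$best_position
    elm_fit(X, y, hidden_count = hidden_count,
            input_weights = matrix(theta[seq_len(hidden_count * p)],
                                   nrow = hidden_count),
            hidden_biases = theta[hidden_count * p + seq_len(hidden_count)],
            svd_tol = svd_tol)
  } else {
    bp_fit(X, y, hidden = hidden, init_weights = res$best_position, ...)
  }

  kind <- paste0(if (init_mode == "logistic") "LCSSA" else "SSA", "-",
                 toupper(model_kind))
  structure(list(kind = kind, model = model, tuning = res),
            class = "trained_predictor")
}

#' Train one of the six moisture model variants
#'
#' Convenience dispatcher over the plain and metaheuristic-tuned
#' regressors, named after the six rows of the model-comparison table:
#' `"BP"`, `"SSA-BP"`, `"LCSSA-BP"`, `"ELM"`, `"SSA-ELM"`, `"LCSSA-ELM"`.
#'
#' @param kind Variant name (see above).
#' @param X Feature matrix (temperature, duty cycle, capacitance).
#' @param y Moisture content in percent.
#' @param seed Integer seed controlling all randomness of the variant.
#' @param ... Passed on to [ssa_tune()], [elm_fit()] or [bp_fit()].
#' @return A `trained_predictor`.
#' @export
train_predictor <- function(kind = c("BP", "SSA-BP", "LCSSA-BP",
                                     "ELM", "SSA-ELM", "LCSSA-ELM"),
                            X, y, seed = NULL, ...) {
  kind <- match.arg(kind)
  if (kind %in% c("BP", "ELM")) {
    if (!is.null(seed)) set.seed(seed)
    model <- if (kind == "ELM") elm_fit(X, y, ...) else bp_fit(X, y, ...)
    return(structure(list(kind = kind, model = model, tuning = NULL),
                     class = "trained_predictor"))
  }
  parts <- strsplit(kind, "-", fixed = TRUE)[[1]]
  ssa_tune(model_kind = tolower(parts[2]), X, y,
           init_mode = if (parts[1] == "LCSSA") "logistic" else "uniform",
           seed = seed, ...)
}

#' @export
predict.trained_predictor <- function(object, newdata, ...) {
  predict(object$model, newdata)
}

#' @export
print.trained_predictor <- function(x, ...) {
  cat(sprintf("%s moisture model\n", x$kind))
  print(x$model)
  invisible(x)
}
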