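#' Logistic chaotic map sequence
#'
#' Iterates the logistic map `y[k+1] = a * y[k] * (1 - y[k])` from a seed
#' value. At `a = 4` the map is fully chaotic and its iterates fill `[0, 1]`
#' with the arcsine-shaped invariant density, which is what makes it useful
#' for spreading initial optimizer populations across a search box.
#'
#' @param y0 Initial value, strictly inside `(0, 1)`.
#' @param a Map parameter in `[0, 4]`.
#' @param length Number of iterates to return (the seed itself is not
#'   included).
#' @return Numeric vector of `length` iterates, all in `[0, 1]`.
#' @examples
#' logistic_sequence(0.3, a = 4, length = 3)  # 0.84 0.5376 0.99434496
#' @export
logistic_sequence <- function(y0, a = 4, length = 1L) {
  check_scalar(y0, "y0", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  check_scalar(a, "a", lower = 0, upper = 4)
  length <- as.integer(length)
  stopifnot(length >= 1L)
  out <- numeric(length)
  y <- y0
  for (k in seq_len(length)) {
    y <- a * y * (1 - y)
    out[k] <- y
  }
  out
}

#' Configuration for the sparrow search algorithm
#'
#' Bundles and validates every tunable of the (LC)SSA optimizer. The
#' population is split each iteration into finders (producers, the
#' best-ranked fraction), joiners (scroungers, the rest), and a randomly
#' drawn set of scouts (early warners, re-sampled every iteration).
#'
#' @param dims Dimension of the search space.
#' @param lower,upper Bound vectors (length `dims`, or scalars recycled).
#' @param pop_size Number of sparrows n (>= 4).
#' @param max_iters Maximum iterations T (>= 1).
#' @param safety_value Safety threshold ST in `[0.5, 1]` of the finder rule.
#' @param finder_fraction Fraction of the population acting as finders,
#'   in (0, 1).
#' @param scout_fraction Fraction acting as scouts each iteration, within
#'   the conventional band `[0.10, 0.20]`.
#' @param logistic_a Logistic map parameter for chaotic initialisation;
#'   4 gives the fully chaotic regime.
#' @param init_mode `"uniform"` for i.i.d. uniform initialisation (plain
#'   SSA) or `"logistic"` for chaotic initialisation (LCSSA).
#' @param seed Optional integer seed; when given, [ssa_optimize()] is fully
#'   reproducible.
#' @return An object of class `ssa_config`.
#' @examples
#' cfg <- ssa_config(dims = 2, lower = -1, upper = 1, pop_size = 10)
#' @export
ssa_config <- function(dims, lower, upper,
                       pop_size = 20L, max_iters = 20L,
                       safety_value = 0.8,
                       finder_fraction = 0.2,
                       scout_fraction = 0.2,
                       logistic_a = 4,
                       init_mode = c("uniform", "logistic"),
                       seed = NULL) {
  dims <- as.integer(dims)
  pop_size <- as.integer(pop_size)
  max_iters <- as.integer(max_iters)
  stopifnot(dims >= 1L, pop_size >= 4L, max_iters >= 1L)
  lower <- rep_len(as.numeric(lower), dims)
  upper <- rep_len(as.numeric(upper), dims)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    stop("bounds must be finite with lower < upper elementwise", call. = FALSE)
  }
  check_scalar(safety_value, "safety_value", lower = 0.5, upper = 1)
  check_scalar(finder_fraction, "finder_fraction", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(scout_fraction, "scout_fraction", lower = 0.10, upper = 0.20)
  check_scalar(logistic_a, "logistic_a", lower = 0, upper = 4)
  init_mode <- match.arg(init_mode)
  structure(
    list(dims = dims, lower = lower, upper = upper, pop_size = pop_size,
         max_iters = max_iters, safety_value = safety_value,
         finder_fraction = finder_fraction, scout_fraction = scout_fraction,
         logistic_a = logistic_a, init_mode = init_mode,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "ssa_config"
  )
}

#' Initialise a sparrow population
#'
#' In `"uniform"` mode positions are i.i.d. uniform within the bounds. In
#' `"logistic"` mode each dimension carries its own logistic-map chain
#' (parameter `logistic_a`, seed value drawn uniformly in (0.01, 0.99)
#' avoiding the collapsing points 0.25, 0.5, 0.75) affinely mapped into the
#' bound box, which spreads the initial solutions more evenly over the box.
#' Consumes the global RNG stream; seed it for reproducibility.
#'
#' @param cfg An [ssa_config()] object.
#' @return A `pop_size x dims` numeric matrix of positions within bounds.
#' @export
ssa_init_population <- function(cfg) {
  stopifnot(inherits(cfg, "ssa_config"))
  n <- cfg$pop_size
  d <- cfg$dims
  if (cfg$init_mode == "uniform") {
    X <- matrix(stats::runif(n * d), nrow = n)
  } else {
    X <- matrix(0, nrow = n, ncol = d)
    for (j in seq_len(d)) {
      y0 <- draw_chaos_seed()
      X[, j] <- logistic_sequence(y0, a = cfg$logistic_a, length = n)
    }
  }
  sweep(sweep(X, 2, cfg$upper - cfg$lower, "*"), 2, cfg$lower, "+")
}

# uniform in (0.01, 0.99) avoiding the period-collapsing preimages of the
# logistic fixed points
draw_chaos_seed <- function() {
  repeat {
    y0 <- stats::runif(1, 0.01, 0.99)
    if (min(abs(y0 - c(0.25, 0.5, 0.75))) > 1e-6) return(y0)
  }
}

clip_to_bounds <- function(X, lower, upper) {
  X <- pmax(X, matrix(lower, nrow(X), ncol(X), byrow = TRUE))
  pmin(X, matrix(upper, nrow(X), ncol(X), byrow = TRUE))
}

# Finder (producer) update. `rows` are the finder row indices ordered best
# first; `i` in the rule is the rank within the finders. All random draws
# (scalar alarm R, per-finder alpha, per-coordinate noise Q) are passed in so
# the update itself is deterministic and oracle-checkable.
ssa_update_finders <- function(X, rows, cfg, R, alpha, Q) {
  nF <- length(rows)
  for (i in seq_len(nF)) {
    r <- rows[i]
    if (R < cfg$safety_value) {
      X[r, ] <- X[r, ] * exp(-i / (alpha[i] * cfg$max_iters))
    } else {
      X[r, ] <- X[r, ] + Q[i, ]
    }
  }
  clip_to_bounds(X, cfg$lower, cfg$upper)
}

# Joiner (scrounger) update. `rows` are joiner row indices ordered by
# fitness (best first); their global fitness ranks are nF+1, ..., n. x_p is
# the updated best finder position, x_l the current global worst position.
# A ±1 row with pseudo-inverse A^T/(A A^T) collapses to a common scalar step
# s = sum(|x - x_p| * A)/d added to every coordinate.
ssa_update_joiners <- function(X, rows, n_finders, cfg, x_p, x_l, Q, Asign) {
  n <- cfg$pop_size
  d <- cfg$dims
  for (k in seq_along(rows)) {
    r <- rows[k]
    i <- n_finders + k  # global fitness rank of this joiner
    if (i > n / 2) {
      X[r, ] <- Q[k, ] * exp((x_l - X[r, ]) / i^2)
    } else {
      s <- sum(abs(X[r, ] - x_p) * Asign[k, ]) / d
      X[r, ] <- x_p + s
    }
  }
  clip_to_bounds(X, cfg$lower, cfg$upper)
}

# Scout (early-warner) update. `rows` are the sampled scout indices; fitness,
# global best/worst refer to the population snapshot at the start of the
# iteration. beta ~ N(0,1) and K ~ U[-1,1] are per-scout scalars; eps guards
# the denominator when f_i == f_w.
ssa_update_scouts <- function(X, rows, fitness, x_b, f_g, x_l, f_w, cfg,
                              beta, K, eps = 1e-50) {
  for (k in seq_along(rows)) {
    r <- rows[k]
    if (fitness[r] > f_g) {
      X[r, ] <- x_b + beta[k] * abs(X[r, ] - x_b)
    } else {
      X[r, ] <- X[r, ] + K[k] * (abs(X[r, ] - x_l) / ((fitness[r] - f_w) + eps))
    }
  }
  clip_to_bounds(X, cfg$lower, cfg$upper)
}

#' Minimise an objective with the sparrow search algorithm
#'
#' Runs SSA (or LCSSA when `cfg$init_mode == "logistic"`) on a box-bounded
#' minimisation problem. Each iteration: (1) sort the population by fitness
#' (ties broken by index); (2) update the best `finder_fraction` as finders —
#' on a safe iteration (alarm draw R below `safety_value`) each finder i
#' contracts as `x * exp(-i/(alpha*T))`, otherwise it takes a Gaussian step;
#' (3) update the remaining joiners — the worse half jumps near the global
#' worst with `Q * exp((x_worst - x)/i^2)`, the better half steps around the
#' best finder along a random ±1 direction; (4) a fresh random
#' `scout_fraction` of sparrows reacts to danger relative to the global
#' best/worst; (5) all positions are clipped to the bounds and re-evaluated.
#' The reported optimum is elitist: the best position ever evaluated.
#'
#' Random draws occur in a fixed order per iteration (alarm R, finder
#' alpha/Q, joiner Q/±1 rows, scout indices/beta/K), so runs are exactly
#' reproducible given `cfg$seed`.
#'
#' @param objective Function mapping a length-`dims` numeric vector to a
#'   scalar. Non-finite values are treated as `+Inf`.
#' @param cfg An [ssa_config()] object.
#' @return An object of class `ssa_result`: list with `best_position`,
#'   `best_fitness`, `history` (per-iteration elitist best, non-increasing,
#'   length `max_iters`), and `evaluations`.
#' @examples
#' cfg <- ssa_config(dims = 5, lower = -100, upper = 100,
#'                   pop_size = 20, max_iters = 15, seed = 1)
#' res <- ssa_optimize(function(x) sum(x^2), cfg)
#' res$best_fitness
#' @export
ssa_optimize <- function(objective, cfg) {
  stopifnot(inherits(cfg, "ssa_config"), is.function(objective))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$pop_size
  d <- cfg$dims

  eval_all <- function(X) {
    f <- apply(X, 1, function(x) {
      v <- objective(x)
      if (!is.finite(v)) Inf else as.numeric(v)
    })
    as.numeric(f)
  }

  X <- ssa_init_population(cfg)
  fitness <- eval_all(X)
  evaluations <- n

  best_i <- which.min(fitness)
  best_position <- X[best_i, ]
  best_fitness <- fitness[best_i]
  history <- numeric(cfg$max_iters)

  n_finders <- max(1L, round(cfg$finder_fraction * n))
  n_finders <- min(n_finders, n - 1L)  # keep at least one joiner
  n_scouts <- max(1L, round(cfg$scout_fraction * n))

  for (t in seq_len(cfg$max_iters)) {
    ord <- order(fitness)  # stable: ties broken by lower index
    f_g <- fitness[ord[1]]
    f_w <- fitness[ord[n]]
    x_b <- X[ord[1], ]
    x_l <- X[ord[n], ]

    # finders
    R <- stats::runif(1)
    alpha <- stats::runif(n_finders)
    Qf <- matrix(stats::rnorm(n_finders * d), nrow = n_finders)
    X <- ssa_update_finders(X, ord[seq_len(n_finders)], cfg, R, alpha, Qf)
    x_p <- X[ord[1], ]  # updated position of the best finder

    # joiners
    jrows <- ord[(n_finders + 1L):n]
    Qj <- matrix(stats::rnorm(length(jrows) * d), nrow = length(jrows))
    Asign <- matrix(sample(c(-1, 1), length(jrows) * d, replace = TRUE),
                    nrow = length(jrows))
    X <- ssa_update_joiners(X, jrows, n_finders, cfg, x_p, x_l, Qj, Asign)

    # scouts
    srows <- sample.int(n, n_scouts)
    beta <- stats::rnorm(n_scouts)
    K <- stats::runif(n_scouts, -1, 1)
    X <- ssa_update_scouts(X, srows, fitness, x_b, f_g, x_l, f_w, cfg, beta, K)

    fitness <- eval_all(X)
    evaluations <- evaluations + n
    it_best <- which.min(fitness)
    if (fitness[it_best] < best_fitness) {
      best_fitness <- fitness[it_best]
      best_position <- X[it_best, ]
    }
    history[t] <- best_fitness
  }

  structure(
    list(best_position = best_position, best_fitness = best_fitness,
         history = history, evaluations = evaluations),
    class = "ssa_result"
  )
}

#' @export
print.ssa_result <- function(x, ...) {
  cat(sprintf("SSA result: best fitness %.6g after %d evaluations\n",
              x$best_fitness, x$evaluations))
  invisible(x)
}
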