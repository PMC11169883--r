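#' Classic benchmark functions F1-F6
#'
#' The six unimodal/step test functions used to compare SSA with its
#' chaos-initialised variant: F1 sphere, F2 sum plus product of absolute
#' values, F3 rotated hyper-ellipsoid (sum of cumulative-sum squares),
#' F4 max absolute coordinate, F5 Rosenbrock, F6 step (floor) function.
#' All have minimum value 0, at the origin except F5 (at the all-ones
#' point). Search boxes follow the conventional benchmark settings
#' (`[-100, 100]` except F2 `[-10, 10]` and F5 `[-30, 30]`), since no
#' boxes are part of the published protocol.
#'
#' @param name One of `"F1"` ... `"F6"`.
#' @param dims Dimension of the search space (default 30).
#' @return An object of class `benchmark_function`: list with `name`,
#'   `dims`, `lower`, `upper`, `fn`, `optimum_value`, `optimum_location`.
#' @examples
#' f <- benchmark_function("F5", dims = 4)
#' f$fn(f$optimum_location)  # 0
#' @export
benchmark_function <- function(name = c("F1", "F2", "F3", "F4", "F5", "F6"),
                               dims = 30L) {
  name <- match.arg(name)
  dims <- as.integer(dims)
  stopifnot(dims >= (if (name == "F5") 2L else 1L))
  raw <- switch(name,
    F1 = function(x) sum(x^2),
    F2 = function(x) sum(abs(x)) + prod(abs(x)),
    F3 = function(x) sum(cumsum(x)^2),
    F4 = function(x) max(abs(x)),
    F5 = function(x) {
      i <- seq_len(length(x) - 1L)
      sum(100 * (x[i + 1L] - x[i]^2)^2 + (x[i] - 1)^2)
    },
    F6 = function(x) sum(floor(x + 0.5)^2)
  )
  half_width <- switch(name, F2 = 10, F5 = 30, 100)
  fn <- function(x) {
    if (length(x) != dims) {
      stop(sprintf("%s expects a vector of length %d, got %d",
                   name, dims, length(x)), call. = FALSE)
    }
    raw(x)
  }
  structure(
    list(name = name, dims = dims,
         lower = rep(-half_width, dims), upper = rep(half_width, dims),
         fn = fn, optimum_value = 0,
         optimum_location = if (name == "F5") rep(1, dims) else rep(0, dims)),
    class = "benchmark_function"
  )
}

#' Paired-seed comparison of SSA and LCSSA on the benchmark suite
#'
#' Runs plain SSA (uniform initialisation) and LCSSA (logistic chaotic
#' initialisation) on each requested benchmark function with identical
#' seeds, so every difference is attributable to the initialisation. This
#' mirrors the published comparison protocol (population 30, 20 iterations).
#'
#' @param functions Character vector of benchmark names.
#' @param dims Benchmark dimensionality.
#' @param pop_size,max_iters SSA population size and iteration budget.
#' @param n_seeds Number of paired seeds per function.
#' @param seed Master seed from which the paired run seeds are derived.
#' @return A data.frame with columns `fun`, `seed`, `algorithm`
#'   (`"SSA"`/`"LCSSA"`) and `best_fitness`; attribute `"traces"` holds the
#'   per-run convergence histories.
#' @examples
#' cmp <- compare_optimizers(functions = "F1", dims = 5, n_seeds = 3, seed = 1)
#' aggregate(best_fitness ~ algorithm, cmp, median)
#' @export
compare_optimizers <- function(functions = paste0("F", 1:6),
                               dims = 30L, pop_size = 30L, max_iters = 20L,
                               n_seeds = 11L, seed = 1L) {
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_seeds)
  rows <- list()
  traces <- list()
  for (fname in functions) {
    bf <- benchmark_function(fname, dims = dims)
    for (k in seq_len(n_seeds)) {
      for (mode in c("uniform", "logistic")) {
        cfg <- ssa_config(dims = bf$dims, lower = bf$lower, upper = bf$upper,
                          pop_size = pop_size, max_iters = max_iters,
                          init_mode = mode, seed = run_seeds[k])
        res <- ssa_optimize(bf$fn, cfg)
        algo <- if (mode == "uniform") "SSA" else "LCSSA"
        rows[[length(rows) + 1L]] <- data.frame(
          fun = fname, seed = run_seeds[k], algorithm = algo,
          best_fitness = res$best_fitness, stringsAsFactors = FALSE)
        traces[[paste(fname, run_seeds[k], algo, sep = "_")]] <- res$history
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "traces") <- traces
  out
}
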