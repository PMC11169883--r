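test_that("logistic map iterates correctly and stays in [0, 1]", {
  expect_equal(logistic_sequence(0.3, a = 4, length = 3),
               c(0.84, 0.5376, 0.99434496))
  expect_equal(logistic_sequence(0.7, a = 0, length = 5), rep(0, 5))
  # preimage of the fixed point: 0.5 maps to 1 then collapses to 0
  expect_equal(logistic_sequence(0.5, a = 4, length = 3), c(1, 0, 0))
  s <- logistic_sequence(0.123, a = 4, length = 1000)
  expect_true(all(s >= 0 & s <= 1))
  expect_error(logistic_sequence(0, a = 4, length = 2), "y0")
  expect_error(logistic_sequence(1, a = 4, length = 2), "y0")
})

test_that("population initialisation respects bounds and is seed-deterministic", {
  for (mode in c("uniform", "logistic")) {
    cfg <- ssa_config(dims = 4, lower = c(-2, 0, 5, -1), upper = c(2, 1, 6, 0),
                      pop_size = 25, init_mode = mode)
    set.seed(99); X1 <- ssa_init_population(cfg)
    set.seed(99); X2 <- ssa_init_population(cfg)
    expect_identical(X1, X2)
    expect_true(all(sweep(X1, 2, cfg$lower, ">=")))
    expect_true(all(sweep(X1, 2, cfg$upper, "<=")))
  }
})

test_that("chaotic initialisation covers the box like the logistic invariant density", {
  cfg <- ssa_config(dims = 1, lower = 0, upper = 1, pop_size = 500,
                    init_mode = "logistic")
  set.seed(11)
  x <- ssa_init_population(cfg)[, 1]
  # every decile of [0,1] is populated
  expect_true(all(table(cut(x, seq(0, 1, 0.1))) > 0))
  # closer to the arcsine invariant CDF than a degenerate (constant) orbit
  arcsine_cdf <- function(q) 2 / pi * asin(sqrt(q))
  ks_chaos <- suppressWarnings(ks.test(x, arcsine_cdf)$statistic)
  ks_degenerate <- suppressWarnings(ks.test(rep(0.5, 500), arcsine_cdf)$statistic)
  expect_lt(ks_chaos, ks_degenerate)
  expect_lt(ks_chaos, 0.15)
})

test_that("vectorised update rules equal independent scalar-loop oracles", {
  set.seed(3)
  n <- 10; d <- 4
  cfg <- ssa_config(dims = d, lower = -5, upper = 5, pop_size = n,
                    max_iters = 30)
  X <- matrix(runif(n * d, -5, 5), n)
  fitness <- apply(X, 1, function(x) sum(x^2))
  ord <- order(fitness)
  nF <- 3L
  frow <- ord[1:nF]

  for (R in c(0.2, 0.95)) {  # exercise both finder branches
    alpha <- runif(nF); Q <- matrix(rnorm(nF * d), nF)
    got <- capmoist:::ssa_update_finders(X, frow, cfg, R, alpha, Q)
    expect_equal(got, oracle_update_finders(X, frow, cfg, R, alpha, Q))
  }

  jrow <- ord[(nF + 1):n]
  x_p <- X[ord[1], ]; x_l <- X[ord[n], ]
  Qj <- matrix(rnorm(length(jrow) * d), length(jrow))
  A <- matrix(sample(c(-1, 1), length(jrow) * d, TRUE), length(jrow))
  expect_equal(
    capmoist:::ssa_update_joiners(X, jrow, nF, cfg, x_p, x_l, Qj, A),
    oracle_update_joiners(X, jrow, nF, cfg, x_p, x_l, Qj, A))

  srow <- sample(n, 2)
  beta <- rnorm(2); K <- runif(2, -1, 1)
  f_g <- min(fitness); f_w <- max(fitness)
  expect_equal(
    capmoist:::ssa_update_scouts(X, srow, fitness, X[ord[1], ], f_g,
                                 X[ord[n], ], f_w, cfg, beta, K),
    oracle_update_scouts(X, srow, fitness, X[ord[1], ], f_g,
                         X[ord[n], ], f_w, cfg, beta, K))
})

test_that("update rule limit cases behave as the formulas dictate", {
  n <- 8; d <- 3
  cfg <- ssa_config(dims = d, lower = -10, upper = 10, pop_size = n,
                    max_iters = 20)
  X <- matrix(runif(n * d, -9, 9), n)

  # safe branch contracts finder coordinates toward the origin
  got <- capmoist:::ssa_update_finders(X, 1:2, cfg, R = 0.1,
                                       alpha = c(0.5, 0.9),
                                       Q = matrix(0, 2, d))
  expect_true(all(abs(got[1:2, ]) <= abs(X[1:2, ])))

  # alarm branch with zero noise leaves positions unchanged
  got <- capmoist:::ssa_update_finders(X, 1:2, cfg, R = 0.99,
                                       alpha = c(0.5, 0.9),
                                       Q = matrix(0, 2, d))
  expect_equal(got, X)

  # joiner at the producer position takes a zero step (rank <= n/2)
  x_p <- X[3, ]
  X2 <- X; X2[4, ] <- x_p
  got <- capmoist:::ssa_update_joiners(X2, 4L, 1L, cfg, x_p, X[8, ],
                                       Q = matrix(rnorm(d), 1),
                                       Asign = matrix(c(-1, 1, -1), 1))
  expect_equal(got[4, ], x_p)

  # joiner at the worst position with rank > n/2 reduces to a fresh draw Q
  Qrow <- matrix(rnorm(d), 1)
  X3 <- X; X3[7, ] <- X[8, ]
  got <- capmoist:::ssa_update_joiners(X3, 7L, 6L, cfg, x_p, X[8, ],
                                       Q = Qrow, Asign = matrix(1, 1, d))
  expect_equal(got[7, ], pmin(pmax(Qrow[1, ], cfg$lower), cfg$upper))

  # scout at the global best with K = 0 stays put; the f_i == f_w
  # denominator guard keeps the step finite
  fitness <- apply(X, 1, function(x) sum(x^2))
  b <- which.min(fitness); w <- which.max(fitness)
  got <- capmoist:::ssa_update_scouts(X, b, fitness, X[b, ], fitness[b],
                                      X[w, ], fitness[w], cfg,
                                      beta = 1, K = 0)
  expect_equal(got[b, ], X[b, ])
  got <- capmoist:::ssa_update_scouts(X, w, fitness, X[b, ], fitness[b],
                                      X[w, ], fitness[w], cfg,
                                      beta = 1, K = 0.5)
  expect_true(all(is.finite(got[w, ])))
})

test_that("ssa_optimize is elitist, bounded, and reproducible", {
  cfg <- ssa_config(dims = 3, lower = -2, upper = 2, pop_size = 12,
                    max_iters = 25, seed = 5)
  # constant objective: optimum known after the first iteration
  res <- ssa_optimize(function(x) 3.5, cfg)
  expect_equal(res$history[1], 3.5)
  expect_equal(res$best_fitness, 3.5)

  seen <- new.env(); seen$ok <- TRUE
  obj <- function(x) {
    if (any(x < -2 - 1e-12) || any(x > 2 + 1e-12)) seen$ok <- FALSE
    sum((x - 0.5)^2) + rnorm(1, 0, 0.01)  # noisy objective
  }
  res1 <- ssa_optimize(obj, cfg)
  expect_true(seen$ok)                       # every evaluated point in bounds
  expect_true(all(diff(res1$history) <= 0))  # elitist trace
  expect_length(res1$history, cfg$max_iters)
  expect_equal(res1$evaluations, cfg$pop_size * (cfg$max_iters + 1L))

  res2 <- ssa_optimize(obj, cfg)
  expect_identical(res1$best_position, res2$best_position)

  # non-finite objective values are treated as +Inf, not propagated
  res3 <- ssa_optimize(function(x) if (x[1] > 0) NaN else sum(x^2), cfg)
  expect_true(is.finite(res3$best_fitness))
})

test_that("LCSSA solves the sphere to well below 1 at the benchmark budget", {
  finals <- sapply(1:11, function(s) {
    cfg <- ssa_config(dims = 10, lower = -100, upper = 100, pop_size = 30,
                      max_iters = 20, init_mode = "logistic", seed = s)
    ssa_optimize(function(x) sum(x^2), cfg)$best_fitness
  })
  expect_lt(median(finals), 1)
})
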