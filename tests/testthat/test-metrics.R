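test_that("correlation matches the hand-computed definition", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84))
  x <- rnorm(20)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  # invariant under positive affine maps of either argument
  y <- rnorm(20)
  expect_equal(pearson_r(2 * x + 3, y), pearson_r(x, y))
  expect_equal(pearson_r(x, 0.5 * y - 7), pearson_r(x, y))
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("rmse matches its definition and scales linearly", {
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  y <- rnorm(10); yh <- rnorm(10)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(3 * y, 3 * yh), 3 * rmse(y, yh))
  expect_error(rmse(1:3, 1:4), "length mismatch")
})

test_that("RPD from R reproduces the published pairings", {
  expect_equal(rpd_from_r(0), 1)
  expect_equal(rpd_from_r(0.7016), 1.4035, tolerance = 0.001)
  expect_equal(rpd_from_r(0.8022), 1.6751, tolerance = 0.001)
  expect_true(all(diff(rpd_from_r(seq(0, 0.99, 0.01))) > 0))
  expect_error(rpd_from_r(1), "\\|R\\| < 1")
  # classical chemometrics ratio is a separate quantity
  y <- c(1, 2, 3, 4); yh <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(rpd_classic(y, yh), sd(y) / rmse(y, yh))
})

test_that("reliability bands follow the stated thresholds, closed below", {
  expect_equal(reliability_band(c(1.2394, 1.4035, 2.5)),
               c("unreliable", "relatively_reliable", "highly_reliable"))
  expect_equal(reliability_band(1.4), "unreliable")
  expect_equal(reliability_band(2.0), "relatively_reliable")
})

test_that("dataset summaries report count, extremes, mean and SD", {
  s <- summarize_dataset(c(5.64, 23.52))
  expect_equal(s$n_samples, 2)
  expect_equal(s$max, 23.52)
  expect_equal(s$min, 5.64)
  expect_equal(summarize_dataset(rep(7, 5))$sd, 0)
  x <- rnorm(30)
  expect_equal(summarize_dataset(x)$sd, sd(x))
  expect_equal(summarize_dataset(x, sd_type = "population")$sd,
               sd(x) * sqrt(29 / 30))
})

test_that("model reports satisfy the RPD-from-R identity and warn on negative R", {
  set.seed(9)
  y1 <- rnorm(30); p1 <- y1 + rnorm(30, 0, 0.3)
  y2 <- rnorm(20); p2 <- y2 + rnorm(20, 0, 0.5)
  rep <- model_report("toy", y1, p1, y2, p2)
  expect_equal(rep$RPD_C, rpd_from_r(rep$R_C), tolerance = 1e-12)
  expect_equal(rep$RPD_P, rpd_from_r(rep$R_P), tolerance = 1e-12)
  expect_named(rep, c("model", "R_C", "RMSE_C", "RPD_C",
                      "R_P", "RMSE_P", "RPD_P"))
  expect_warning(model_report("bad", y1, -y1 + rnorm(30, 0, 0.2), y2, p2),
                 "negative correlation")
})
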