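test_that("the default factorial campaign has 720 records", {
  camp <- generate_campaign(seed = 1)
  expect_equal(nrow(camp), 720)
  expect_equal(length(unique(camp$moisture_percent)), 16)
  expect_equal(sort(unique(camp$temperature_C)), c(15, 22, 33))
  expect_equal(sort(unique(camp$duty_cycle)), c(0, 1/6, 1/4, 1/3, 1/2))
  expect_true(all(is.finite(camp$capacitance_pF)))
  camp2 <- generate_campaign(seed = 1)
  expect_identical(camp, camp2)
})

test_that("design validation rejects malformed moisture level lists", {
  expect_error(campaign_design(moisture_levels_percent = c(5, 5, 7)),
               "duplicate")
  expect_error(campaign_design(moisture_levels_percent = c(7, 5)), "sorted")
})

test_that("the noiseless generator is anchored to the calibration line", {
  quiet <- noise_model(sigma = 0)
  camp <- generate_campaign(noise = quiet, seed = 1)
  ref <- camp[camp$temperature_C == 22 & camp$duty_cycle == 1/3, ]
  expect_equal(ref$capacitance_pF, linear_calibration(ref$moisture_percent))
  # regressing C on W in the anchor slice recovers the printed coefficients
  fit <- lm(capacitance_pF ~ moisture_percent, data = ref)
  expect_equal(unname(coef(fit)), c(17.28085, 0.30744), tolerance = 1e-9)
  # zero-moisture intercept
  w0 <- generate_campaign(
    campaign_design(moisture_levels_percent = 0, replicates_per_level = 1,
                    temperatures_C = 22, duty_cycles = 1/3),
    quiet, seed = 1)
  expect_equal(w0$capacitance_pF, 17.28085)
})

test_that("noiseless capacitance increases along each design axis", {
  quiet <- noise_model(sigma = 0)
  camp <- generate_campaign(noise = quiet, seed = 1)
  camp <- camp[camp$duty_cycle > 0, ]
  for (tt in unique(camp$temperature_C)) {
    for (v in unique(camp$duty_cycle)) {
      slice <- camp[camp$temperature_C == tt & camp$duty_cycle == v &
                      camp$replicate == 1, ]
      slice <- slice[order(slice$moisture_percent), ]
      expect_true(all(diff(slice$capacitance_pF) > 0))
    }
  }
  for (w in unique(camp$moisture_percent)) {
    by_t <- camp[camp$moisture_percent == w & camp$duty_cycle == 1/2 &
                   camp$replicate == 1, ]
    expect_true(all(diff(by_t$capacitance_pF[order(by_t$temperature_C)]) > 0))
    by_v <- camp[camp$moisture_percent == w & camp$temperature_C == 15 &
                   camp$replicate == 1, ]
    expect_true(all(diff(by_v$capacitance_pF[order(by_v$duty_cycle)]) > 0))
  }
})

test_that("empty-plate records sit at the air baseline", {
  quiet <- noise_model(sigma = 0)
  camp <- generate_campaign(noise = quiet, seed = 1)
  expect_true(all(camp$capacitance_pF[camp$duty_cycle == 0] ==
                    quiet$baseline_air))
})

test_that("the 3:1 split partitions 720 records into 540 + 180", {
  camp <- generate_campaign(seed = 1)
  sp <- split_train_test(camp, seed = 2)
  expect_equal(nrow(sp$train), 540)
  expect_equal(nrow(sp$test), 180)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), camp$sample_id)
  sp2 <- split_train_test(camp, seed = 2)
  expect_identical(sp, sp2)
  # non-divisible counts floor the training size
  sp3 <- split_train_test(camp[1:10, ], ratio = 0.75, seed = 1)
  expect_equal(nrow(sp3$train), 7)
  # stratified option keeps the ratio within groups
  sp4 <- split_train_test(camp, seed = 3, stratify_by = "temperature_C")
  tab <- table(sp4$train$temperature_C)
  expect_true(all(tab == 180))
})

test_that("channel differencing rejects common-mode disturbances", {
  det <- c(27.5, 28.1, 29.0)
  ref <- c(10.2, 10.3, 10.1)
  expect_equal(difference_channels(det, det), rep(0, 3))
  expect_equal(difference_channels(det, rep(0, 3)), det)
  offset <- 2.34  # e.g. a shared temperature drift
  expect_equal(difference_channels(det + offset, ref + offset),
               difference_channels(det, ref))
  expect_error(difference_channels(det, ref[1:2]), "equal length")
})
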