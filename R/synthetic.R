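#' Factorial design of the capacitance measurement campaign
#'
#' The full-factorial layout of the reference measurement campaign: 16
#' wet-basis moisture levels between 5.64% and 23.52% (including the 14.42%
#' as-harvested level), three replicate samples per level, ambient
#' temperatures of 15, 22 and 33 degrees C, and volume duty cycles 0, 1/6,
#' 1/4, 1/3, 1/2 — 720 records in all.
#'
#' @param moisture_levels_percent Sorted vector of distinct moisture levels
#'   in percent.
#' @param replicates_per_level Number of replicate samples per level.
#' @param temperatures_C Ambient temperatures in degrees C.
#' @param duty_cycles Volume duty cycles in `[0, 1]` (0 = empty plates).
#' @return An object of class `campaign_design`.
#' @examples
#' d <- campaign_design()
#' nrow(expand.grid(d$moisture_levels_percent, seq_len(d$replicates_per_level),
#'                  d$temperatures_C, d$duty_cycles))  # 720
#' @export
campaign_design <- function(
    moisture_levels_percent = c(5.64, 8.36, 8.62, 11.65, 12.04, 12.17,
                                13.57, 14.42, 15.99, 16.26, 17.65, 19.52,
                                21.51, 22.58, 23.27, 23.52),
    replicates_per_level = 3L,
    temperatures_C = c(15, 22, 33),
    duty_cycles = c(0, 1/6, 1/4, 1/3, 1/2)) {
  stopifnot(is.numeric(moisture_levels_percent),
            length(moisture_levels_percent) >= 1L,
            all(moisture_levels_percent >= 0),
            all(moisture_levels_percent < 100),
            replicates_per_level >= 1L,
            all(duty_cycles >= 0), all(duty_cycles <= 1))
  if (anyDuplicated(moisture_levels_percent)) {
    stop("duplicate moisture levels are not allowed", call. = FALSE)
  }
  if (is.unsorted(moisture_levels_percent)) {
    stop("moisture levels must be sorted increasing", call. = FALSE)
  }
  structure(
    list(moisture_levels_percent = moisture_levels_percent,
         replicates_per_level = as.integer(replicates_per_level),
         temperatures_C = temperatures_C,
         duty_cycles = duty_cycles),
    class = "campaign_design"
  )
}

#' Sensor noise and environmental-response model
#'
#' Parameters of the synthetic measurement model. The noiseless response at
#' 22 degrees C and duty cycle 1/3 is anchored to the empirical calibration
#' line [linear_calibration()]; temperature and duty-cycle departures act as
#' multiplicative monotone factors (capacitance increases with both), with
#' the temperature effect amplified at high moisture. None of the
#' coefficients below are measured values — they encode the qualitative
#' trends of the reference campaign:
#' `C = (0.30744 W + 17.28085) * (1 + k_T (T - 22)(1 + lambda W)) *
#'  (1 + k_v (v - 1/3)) + N(0, sigma^2)` for duty cycle `v > 0`, and
#' `C = baseline_air + N(0, sigma^2)` for `v = 0` (empty plates: the
#' differenced channel carries no grain signal).
#'
#' @param sigma Gaussian measurement noise SD in sensor units (pF).
#' @param k_T Temperature coefficient per degree C (> 0).
#' @param lambda Moisture amplification of the temperature effect per
#'   percent moisture (> 0).
#' @param k_v Duty-cycle coefficient (> 0).
#' @param baseline_air Mean differenced capacitance of the empty cell (pF).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.4, k_T = 0.004, lambda = 0.05,
                        k_v = 0.6, baseline_air = 10.0) {
  check_scalar(sigma, "sigma", lower = 0)
  check_scalar(k_T, "k_T", lower = 0, open_lower = TRUE)
  check_scalar(lambda, "lambda", lower = 0, open_lower = TRUE)
  check_scalar(k_v, "k_v", lower = 0, open_lower = TRUE)
  check_scalar(baseline_air, "baseline_air", lower = 0)
  structure(list(sigma = sigma, k_T = k_T, lambda = lambda, k_v = k_v,
                 baseline_air = baseline_air),
            class = "noise_model")
}

# noiseless mean response of the synthetic sensor model
campaign_mean_capacitance <- function(w_percent, temperature_C, duty_cycle,
                                      noise = noise_model()) {
  base <- linear_calibration(w_percent)
  temp_factor <- 1 + noise$k_T * (temperature_C - 22) *
    (1 + noise$lambda * w_percent)
  duty_factor <- 1 + noise$k_v * (duty_cycle - 1/3)
  ifelse(duty_cycle > 0, base * temp_factor * duty_factor, noise$baseline_air)
}

#' Generate a synthetic measurement campaign
#'
#' Simulates the full factorial campaign of [campaign_design()] under the
#' sensor model of [noise_model()]. Deterministic given `seed`. With the
#' defaults the result has 720 rows, and at 22 degrees C and duty cycle 1/3
#' the noiseless mean capacitance reproduces the empirical calibration line
#' exactly.
#'
#' @param design A [campaign_design()].
#' @param noise A [noise_model()].
#' @param seed Optional integer seed.
#' @return A data.frame with columns `sample_id`, `moisture_percent`,
#'   `temperature_C`, `duty_cycle`, `capacitance_pF`, `replicate`.
#' @examples
#' camp <- generate_campaign(seed = 1)
#' nrow(camp)  # 720
#' @export
generate_campaign <- function(design = campaign_design(),
                              noise = noise_model(), seed = NULL) {
  stopifnot(inherits(design, "campaign_design"), inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(
    moisture_percent = design$moisture_levels_percent,
    replicate = seq_len(design$replicates_per_level),
    temperature_C = design$temperatures_C,
    duty_cycle = design$duty_cycles,
    KEEP.OUT.ATTRS = FALSE
  )
  mu <- campaign_mean_capacitance(grid$moisture_percent, grid$temperature_C,
                                  grid$duty_cycle, noise)
  eta <- stats::rnorm(nrow(grid), 0, noise$sigma)
  data.frame(
    sample_id = sprintf("S%04d", seq_len(nrow(grid))),
    moisture_percent = grid$moisture_percent,
    temperature_C = grid$temperature_C,
    duty_cycle = grid$duty_cycle,
    capacitance_pF = mu + eta,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
}

#' Random 3:1 split into training and prediction sets
#'
#' Randomly assigns `ratio` of the records to the training set and the rest
#' to the prediction set (simple random split; 720 records give 540/180).
#' When the count is not divisible, the training size is rounded down.
#'
#' @param records Data.frame of measurement records.
#' @param ratio Training fraction (default 3/4).
#' @param seed Optional integer seed.
#' @param stratify_by Optional column name; when given, the split is drawn
#'   within each level of that column (off by default).
#' @return List with elements `train` and `test` (disjoint, union = input).
#' @examples
#' sp <- split_train_test(generate_campaign(seed = 1), seed = 2)
#' c(nrow(sp$train), nrow(sp$test))  # 540 180
#' @export
split_train_test <- function(records, ratio = 0.75, seed = NULL,
                             stratify_by = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 2L,
            ratio > 0, ratio < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  if (is.null(stratify_by)) {
    idx <- sample.int(n, floor(n * ratio))
  } else {
    stopifnot(stratify_by %in% names(records))
    groups <- split(seq_len(n), records[[stratify_by]])
    idx <- unlist(lapply(groups, function(g) {
      sample(g, floor(length(g) * ratio))
    }), use.names = FALSE)
  }
  list(train = records[sort(idx), , drop = FALSE],
       test = records[setdiff(seq_len(n), sort(idx)), , drop = FALSE])
}

#' Differential channel subtraction
#'
#' Subtracts the reference (air) channel from the detection channel, the
#' common-mode rejection step of a differential capacitive sensor: any
#' disturbance affecting both channels equally cancels.
#'
#' @param detection Detection-channel capacitances.
#' @param reference Reference-channel capacitances (same length).
#' @return Elementwise `detection - reference`.
#' @examples
#' difference_channels(c(27.5, 28.1), c(10.2, 10.3))
#' @export
difference_channels <- function(detection, reference) {
  if (length(detection) != length(reference)) {
    stop("detection and reference channels must have equal length",
         call. = FALSE)
  }
  detection - reference
}
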