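#' Pearson correlation coefficient R
#'
#' The correlation between measured and predicted moisture used as the
#' primary model-quality score. Thin validated wrapper around
#' [stats::cor()].
#'
#' @param x,y Numeric vectors of equal length (>= 2) with nonzero variance.
#' @return R in `[-1, 1]`.
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 2, 4))  # 9 / sqrt(84)
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in an argument", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Root mean square error
#'
#' @param y Observed values.
#' @param y_hat Predicted values (same length).
#' @return `sqrt(mean((y - y_hat)^2))`.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    stop("length mismatch between observed and predicted", call. = FALSE)
  }
  sqrt(mean((y - y_hat)^2))
}

#' Ratio performance deviation from a correlation coefficient
#'
#' The RPD convention used in this modelling suite is a function of the
#' correlation alone: `RPD = 1 / sqrt(1 - R^2)`. It equals the classical
#' SD/RMSE ratio when predictions come from a least-squares calibration on
#' the same data, and is always >= 1, increasing in `|R|`. For the classical
#' ratio on held-out data see [rpd_classic()].
#'
#' @param r Correlation coefficient with `|r| < 1` (vectorised).
#' @return RPD values >= 1.
#' @examples
#' rpd_from_r(0.7016)  # about 1.4035
#' @export
rpd_from_r <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("RPD requires |R| < 1", call. = FALSE)
  }
  1 / sqrt(1 - r^2)
}

#' Classical ratio of performance to deviation
#'
#' The chemometrics convention `RPD = sd(y) / RMSE`. Kept clearly separate
#' from the correlation-based [rpd_from_r()] used in the main reports.
#'
#' @param y Observed values.
#' @param y_hat Predicted values.
#' @return `sd(y) / rmse(y, y_hat)`.
#' @export
rpd_classic <- function(y, y_hat) {
  stats::sd(y) / rmse(y, y_hat)
}

#' Reliability band of a calibration model from its RPD
#'
#' Models with RPD below 1.4 are regarded as unreliable, between 1.4 and
#' 2.0 as relatively reliable, and above 2.0 as highly reliable. Boundary
#' values (exactly 1.4 or 2.0) are assigned to the lower band.
#'
#' @param rpd RPD values >= 1 (vectorised).
#' @return Character vector with levels `"unreliable"`,
#'   `"relatively_reliable"`, `"highly_reliable"`.
#' @examples
#' reliability_band(c(1.2394, 1.4035, 2.5))
#' @export
reliability_band <- function(rpd) {
  stopifnot(is.numeric(rpd), all(rpd >= 1))
  ifelse(rpd <= 1.4, "unreliable",
         ifelse(rpd <= 2.0, "relatively_reliable", "highly_reliable"))
}

#' Summary statistics of a moisture data set
#'
#' The count/max/min/mean/SD row used to describe the training and
#' prediction splits.
#'
#' @param moisture Numeric vector of moisture contents in percent.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return One-row data.frame with columns `n_samples`, `max`, `min`,
#'   `mean`, `sd`.
#' @export
summarize_dataset <- function(moisture, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.numeric(moisture), length(moisture) >= 1L)
  n <- length(moisture)
  s <- if (n == 1L) 0 else stats::sd(moisture)
  if (sd_type == "population" && n > 1L) s <- s * sqrt((n - 1) / n)
  data.frame(n_samples = n, max = max(moisture), min = min(moisture),
             mean = mean(moisture), sd = s)
}

#' Six-metric evaluation row for one model variant
#'
#' Computes the training/prediction R, RMSE and RPD triplets for a fitted
#' variant — one row of the model-comparison table. RPD is derived from R
#' via [rpd_from_r()], so the RPD-from-R identity holds exactly for every
#' row. A negative correlation is reported verbatim with a warning.
#'
#' @param model_name Label for the row.
#' @param y_train,yhat_train Observed and predicted moisture on the
#'   training set.
#' @param y_test,yhat_test Observed and predicted moisture on the
#'   prediction set.
#' @return One-row data.frame with columns `model`, `R_C`, `RMSE_C`,
#'   `RPD_C`, `R_P`, `RMSE_P`, `RPD_P` (C = calibration/training,
#'   P = prediction).
#' @export
model_report <- function(model_name, y_train, yhat_train, y_test, yhat_test) {
  r_c <- pearson_r(y_train, yhat_train)
  r_p <- pearson_r(y_test, yhat_test)
  if (r_c < 0 || r_p < 0) {
    warning(sprintf("negative correlation for model %s", model_name),
            call. = FALSE)
  }
  data.frame(model = model_name,
             R_C = r_c, RMSE_C = rmse(y_train, yhat_train),
             RPD_C = rpd_from_r(r_c),
             R_P = r_p, RMSE_P = rmse(y_test, yhat_test),
             RPD_P = rpd_from_r(r_p),
             stringsAsFactors = FALSE)
}
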