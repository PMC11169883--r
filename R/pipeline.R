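MODEL_VARIANTS <- c("BP", "SSA-BP", "LCSSA-BP", "ELM", "SSA-ELM", "LCSSA-ELM")

#' Configuration of a full moisture-modelling experiment
#'
#' Collects everything needed to reproduce a simulate - split - fit -
#' report run: the campaign design, the sensor noise model, the optimizer
#' and regressor hyperparameters, and the seeds. A single master `seed`
#' fans out deterministically to `campaign_seed`, `split_seed` and
#' `model_seed` unless those are given explicitly, so changing only
#' `model_seed` re-fits the models on an untouched campaign and split.
#'
#' @param seed Master integer seed.
#' @param campaign_seed,split_seed,model_seed Optional stage seeds
#'   overriding the fan-out.
#' @param design A [campaign_design()].
#' @param noise A [noise_model()].
#' @param variants Model variants to fit (default all six).
#' @param ssa_pop_size,ssa_max_iters Sparrow population size and iteration
#'   budget for the tuned variants (default 20/20).
#' @param elm_hidden ELM hidden-layer size (default 100).
#' @param bp_hidden,bp_learning_rate,bp_max_epochs BP topology and training
#'   controls.
#' @param include_empty_duty Keep duty-cycle-0 (empty plate) records in the
#'   regression stage. They carry no grain signal by construction and are
#'   excluded by default; the campaign itself always contains them.
#' @param train_ratio Training fraction of the random split (default 3/4).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              campaign_seed = NULL, split_seed = NULL,
                              model_seed = NULL,
                              design = campaign_design(),
                              noise = noise_model(),
                              variants = MODEL_VARIANTS,
                              ssa_pop_size = 20L, ssa_max_iters = 20L,
                              elm_hidden = 100L,
                              bp_hidden = 5L, bp_learning_rate = 0.5,
                              bp_max_epochs = 5000L,
                              include_empty_duty = FALSE,
                              train_ratio = 0.75) {
  stopifnot(all(variants %in% MODEL_VARIANTS))
  seed <- as.integer(seed)
  derived <- derive_seeds(seed)
  structure(
    list(seed = seed,
         campaign_seed = as.integer(campaign_seed %||% derived[1]),
         split_seed = as.integer(split_seed %||% derived[2]),
         model_seed = as.integer(model_seed %||% derived[3]),
         design = design, noise = noise, variants = variants,
         ssa_pop_size = as.integer(ssa_pop_size),
         ssa_max_iters = as.integer(ssa_max_iters),
         elm_hidden = as.integer(elm_hidden),
         bp_hidden = as.integer(bp_hidden),
         bp_learning_rate = bp_learning_rate,
         bp_max_epochs = as.integer(bp_max_epochs),
         include_empty_duty = isTRUE(include_empty_duty),
         train_ratio = train_ratio),
    class = "experiment_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one master seed -> three independent stage seeds (all < 2^31)
derive_seeds <- function(seed) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 3L)
}

#' Run the end-to-end moisture modelling experiment
#'
#' Generates a synthetic campaign, splits it 3:1 into training and
#' prediction sets, fits the requested model variants on the shared split
#' (temperature, duty cycle and capacitance as predictors; moisture percent
#' as response), and assembles the six-metric comparison table plus the
#' per-split summary statistics. Fully reproducible from the configuration.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, [write_report()] is called
#'   on the result.
#' @return An object of class `experiment_result`: list with `summary`
#'   (training/prediction moisture statistics), `report` (one
#'   [model_report()] row per variant), `traces` (optimizer fitness traces
#'   for the tuned variants), `seeds`, and `config`.
#' @examples
#' \donttest{
#' cfg <- experiment_config(seed = 7, variants = c("ELM", "LCSSA-ELM"),
#'                          ssa_max_iters = 5, elm_hidden = 20)
#' res <- run_experiment(cfg)
#' res$report
#' }
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  campaign <- generate_campaign(config$design, config$noise,
                                seed = config$campaign_seed)
  split <- split_train_test(campaign, ratio = config$train_ratio,
                            seed = config$split_seed)
  summary_tab <- rbind(
    cbind(data_set = "Training set",
          summarize_dataset(split$train$moisture_percent)),
    cbind(data_set = "Prediction set",
          summarize_dataset(split$test$moisture_percent))
  )

  model_rows <- function(df) {
    if (!config$include_empty_duty) df <- df[df$duty_cycle > 0, , drop = FALSE]
    df
  }
  train <- model_rows(split$train)
  test <- model_rows(split$test)
  features <- function(df) {
    as.matrix(df[, c("temperature_C", "duty_cycle", "capacitance_pF")])
  }
  Xtr <- features(train); ytr <- train$moisture_percent
  Xte <- features(test);  yte <- test$moisture_percent

  # one seed per regressor family: the SSA- and LCSSA-tuned variants of a
  # family share it, so they form true seed pairs differing only in the
  # population initialisation mode
  set.seed(config$model_seed)
  family_seeds <- stats::setNames(
    sample.int(.Machine$integer.max - 1L, 2L), c("BP", "ELM"))

  reports <- list()
  traces <- list()
  for (i in seq_along(config$variants)) {
    kind <- config$variants[i]
    family <- if (grepl("ELM", kind)) "ELM" else "BP"
    args <- list(kind = kind, X = Xtr, y = ytr,
                 seed = family_seeds[[family]])
    if (grepl("ELM", kind)) {
      args$hidden_count <- config$elm_hidden
    } else {
      args$hidden <- config$bp_hidden
      args$learning_rate <- config$bp_learning_rate
      args$max_epochs <- config$bp_max_epochs
    }
    if (grepl("SSA", kind)) {
      args$pop_size <- config$ssa_pop_size
      args$max_iters <- config$ssa_max_iters
    }
    tp <- do.call(train_predictor, args)
    reports[[kind]] <- model_report(kind, ytr, predict(tp, Xtr),
                                    yte, predict(tp, Xte))
    if (!is.null(tp$tuning)) traces[[kind]] <- tp$tuning$history
  }

  result <- structure(
    list(summary = summary_tab,
         report = do.call(rbind, c(reports, make.row.names = FALSE)),
         traces = traces,
         seeds = c(campaign = config$campaign_seed,
                   split = config$split_seed, model = config$model_seed),
         config = config),
    class = "experiment_result"
  )
  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Moisture modelling experiment\n\nData set summary:\n")
  print(x$summary, row.names = FALSE, digits = 6)
  cat("\nModel comparison (R / RMSE / RPD, training C and prediction P):\n")
  rep4 <- x$report
  rep4[-1] <- lapply(rep4[-1], round, 4)
  print(rep4, row.names = FALSE)
  invisible(x)
}

#' Read measurement records from CSV
#'
#' Expects the campaign schema (`sample_id`, `moisture_percent`,
#' `temperature_C`, `duty_cycle`, `capacitance_pF`); additional columns are
#' preserved. Decimal parsing is locale-independent (C locale dot).
#'
#' @param path CSV file path.
#' @return Data.frame of measurement records.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "moisture_percent", "temperature_C",
                "duty_cycle", "capacitance_pF")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) stop("no measurement rows in file", call. = FALSE)
  num_cols <- setdiff(required, "sample_id")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf("malformed numeric value in column `%s`, data line %d",
                   col, bad[1]), call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

#' Write measurement records to CSV
#'
#' @param records Data.frame of measurement records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write an experiment report to disk
#'
#' Emits `report.csv` (metrics rounded to 4 decimals, the tabular
#' convention), `report_full.csv` (full precision sidecar), `summary.csv`,
#' per-variant optimizer traces under `traces/`, and a `provenance.yaml`
#' block recording seeds and configuration.
#'
#' @param result An [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rounded <- result$report
  rounded[-1] <- lapply(rounded[-1], round, 4)
  utils::write.csv(rounded, file.path(dir, "report.csv"), row.names = FALSE)
  utils::write.csv(result$report, file.path(dir, "report_full.csv"),
                   row.names = FALSE)
  utils::write.csv(result$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (length(result$traces) > 0) {
    dir.create(file.path(dir, "traces"), showWarnings = FALSE)
    for (kind in names(result$traces)) {
      utils::write.csv(
        data.frame(iteration = seq_along(result$traces[[kind]]),
                   best_fitness = result$traces[[kind]]),
        file.path(dir, "traces", paste0(kind, ".csv")), row.names = FALSE)
    }
  }
  prov <- list(seeds = as.list(result$seeds),
               config = config_to_list(result$config),
               package_version = as.character(utils::packageVersion("capmoist")))
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

# --- config (de)serialisation --------------------------------------------

config_to_list <- function(config) {
  list(
    seed = config$seed,
    campaign_seed = config$campaign_seed,
    split_seed = config$split_seed,
    model_seed = config$model_seed,
    campaign = list(
      moisture_levels_percent = config$design$moisture_levels_percent,
      replicates_per_level = config$design$replicates_per_level,
      temperatures_C = config$design$temperatures_C,
      duty_cycles = config$design$duty_cycles,
      sigma = config$noise$sigma, k_T = config$noise$k_T,
      lambda = config$noise$lambda, k_v = config$noise$k_v,
      baseline_air = config$noise$baseline_air),
    ssa = list(pop_size = config$ssa_pop_size,
               max_iters = config$ssa_max_iters),
    models = list(variants = config$variants,
                  elm_hidden = config$elm_hidden,
                  bp_hidden = config$bp_hidden,
                  bp_learning_rate = config$bp_learning_rate,
                  bp_max_epochs = config$bp_max_epochs),
    pipeline = list(include_empty_duty = config$include_empty_duty,
                    train_ratio = config$train_ratio)
  )
}

#' Write an experiment configuration to a YAML file
#'
#' @param config An [experiment_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(config_to_list(config), path,
                   precision = 15L)
  invisible(path)
}

#' Read an experiment configuration from a YAML file
#'
#' @param path YAML file written by [write_experiment_config()] (or edited
#'   by hand with the same keys; missing keys fall back to defaults).
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  cam <- x$campaign %||% list()
  dd <- campaign_design()
  nd <- noise_model()
  design <- campaign_design(
    moisture_levels_percent = cam$moisture_levels_percent %||%
      dd$moisture_levels_percent,
    replicates_per_level = cam$replicates_per_level %||%
      dd$replicates_per_level,
    temperatures_C = cam$temperatures_C %||% dd$temperatures_C,
    duty_cycles = cam$duty_cycles %||% dd$duty_cycles)
  noise <- noise_model(sigma = cam$sigma %||% nd$sigma,
                       k_T = cam$k_T %||% nd$k_T,
                       lambda = cam$lambda %||% nd$lambda,
                       k_v = cam$k_v %||% nd$k_v,
                       baseline_air = cam$baseline_air %||% nd$baseline_air)
  experiment_config(
    seed = x$seed %||% 1L,
    campaign_seed = x$campaign_seed, split_seed = x$split_seed,
    model_seed = x$model_seed,
    design = design, noise = noise,
    variants = x$models$variants %||% MODEL_VARIANTS,
    ssa_pop_size = x$ssa$pop_size %||% 20L,
    ssa_max_iters = x$ssa$max_iters %||% 20L,
    elm_hidden = x$models$elm_hidden %||% 100L,
    bp_hidden = x$models$bp_hidden %||% 5L,
    bp_learning_rate = x$models$bp_learning_rate %||% 0.5,
    bp_max_epochs = x$models$bp_max_epochs %||% 5000L,
    include_empty_duty = x$pipeline$include_empty_duty %||% FALSE,
    train_ratio = x$pipeline$train_ratio %||% 0.75)
}
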