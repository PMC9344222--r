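#' Pipeline configuration
#'
#' Aggregates every tunable of the full analysis: cohort source (a
#' [cohort_spec()] for simulation, or a user CSV plus JSON schema sidecar),
#' master seed, train fraction, stability and penalty settings, evaluation
#' span, and the elastic-net mixing values for the post-hoc sensitivity
#' rerun.
#'
#' @param cohort A `cohort_spec` to simulate from, or `NULL` when reading
#'   from files.
#' @param cohort_csv,cohort_schema File paths for user data (ignored when
#'   `cohort` is given).
#' @param master_seed Integer master seed; every stage seed derives from it.
#' @param split_fraction Training fraction (default 0.7).
#' @param era_cutoff Collection-year cutoff (default 2008); set `NULL` to
#'   skip era filtering.
#' @param stability A [stability_config()] (its `seed` is overridden by a
#'   derived seed).
#' @param penalty A [penalty_config()].
#' @param span LOESS span for calibration (default 0.3).
#' @param comparison_alphas Elastic-net mixing values for the sensitivity
#'   rerun (default 0.5); empty vector disables it.
#' @param scaling One of `"full-sample"` (z-scale before splitting, the
#'   replicated convention) or `"train-only"` (leakage-safe: scale on the
#'   training rows and apply those parameters to the test rows).
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = NULL, cohort_csv = NULL, cohort_schema = NULL,
                       master_seed = 1L, split_fraction = 0.7,
                       era_cutoff = 2008,
                       stability = stability_config(B = 200),
                       penalty = penalty_config(),
                       span = 0.3, comparison_alphas = 0.5,
                       scaling = c("full-sample", "train-only")) {
  scaling <- match.arg(scaling)
  if (is.null(cohort) && is.null(cohort_csv))
    stop("provide either a cohort_spec or a cohort_csv path", call. = FALSE)
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_spec"))
  stopifnot(inherits(stability, "stability_config"),
            inherits(penalty, "penalty_config"),
            split_fraction > 0, split_fraction < 1, span > 0, span <= 1)
  structure(list(cohort = cohort, cohort_csv = cohort_csv,
                 cohort_schema = cohort_schema,
                 master_seed = as.integer(master_seed),
                 split_fraction = split_fraction, era_cutoff = era_cutoff,
                 stability = stability, penalty = penalty, span = span,
                 comparison_alphas = comparison_alphas, scaling = scaling),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields mirror [run_config()] arguments; `stability:` and
#' `penalty:` sub-maps mirror [stability_config()] and [penalty_config()].
#' A `cohort: default` entry uses [default_cohort_spec()] with optional
#' `n`, `noise_sd_log`, `missing_rate`, `era_fraction_pre_cutoff` overrides.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(y$cohort)) {
    if (identical(y$cohort, "default")) {
      cohort <- default_cohort_spec()
    } else if (is.list(y$cohort)) {
      # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
      names(y$cohort)[names(y$cohort) == "FALSE"] <- "n"
      cohort <- do.call(default_cohort_spec, y$cohort)
    }
  }
  args <- list(cohort = cohort, cohort_csv = y$cohort_csv,
               cohort_schema = y$cohort_schema)
  for (f in c("master_seed", "split_fraction", "era_cutoff", "span",
              "comparison_alphas", "scaling"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$stability))
    args$stability <- do.call(stability_config, y$stability)
  if (!is.null(y$penalty))
    args$penalty <- do.call(penalty_config, y$penalty)
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Generate (or load) the cohort, filter by era, listwise-delete, encode,
#' split 70:30, run bootstrap stability selection on the training design,
#' refit the selected predictors by least squares, score the held-out set,
#' and rerun selection at each comparison elastic-net alpha with a
#' selected-set agreement report.  All result files are byte-identical across
#' reruns of the same config (stage timings go to a separate `timings.log`).
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return A `pipeline_result` list: `cohort_n`, `analysis_n`, `split`,
#'   `stability`, `refit`, `calibration` (NULL when nothing was selected),
#'   `comparisons`, `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    t0 <<- proc.time()[["elapsed"]]
  }
  seeds <- .derive_seeds(cfg$master_seed, 4L)
  seed_generate <- seeds[1L, 1L]
  seed_missing <- seeds[2L, 1L]
  seed_split <- seeds[3L, 1L]
  seed_stab <- seeds[4L, 1L]

  # --- cohort ---------------------------------------------------------------
  if (!is.null(cfg$cohort)) {
    cohort <- generate_cohort(cfg$cohort, seed = seed_generate)
    if (cfg$cohort$missing_rate > 0)
      cohort <- inject_missingness(cohort, cfg$cohort$missing_rate,
                                   seed = seed_missing)
  } else {
    schema <- cfg$cohort_schema %||% sub("\\.csv$", ".schema.json", cfg$cohort_csv)
    cohort <- read_cohort(cfg$cohort_csv, schema)
  }
  cohort_n <- nrow(cohort)
  tick("cohort")

  # --- preprocess -----------------------------------------------------------
  if (!is.null(cfg$era_cutoff)) cohort <- filter_era(cohort, cfg$era_cutoff)
  cohort <- listwise_delete(cohort)
  n <- nrow(cohort)
  if (n < 2L) stop("pipeline aborted at stage 'preprocess': too few complete rows",
                   call. = FALSE)
  split <- split_cohort(n, cfg$split_fraction, seed = seed_split)
  if (cfg$scaling == "full-sample") {
    dm <- encode(cohort)
    X_train <- dm$X[split$train_idx, , drop = FALSE]
    X_test <- dm$X[split$test_idx, , drop = FALSE]
    y_train <- dm$y_log[split$train_idx]
    y_test <- dm$y_log[split$test_idx]
    column_map <- dm$column_map
  } else {
    dm_tr <- encode(cohort[split$train_idx, , drop = FALSE])
    dm_te <- encode(cohort[split$test_idx, , drop = FALSE],
                    scaling_params = dm_tr$scaling_params)
    X_train <- dm_tr$X; y_train <- dm_tr$y_log
    X_test <- dm_te$X; y_test <- dm_te$y_log
    column_map <- dm_tr$column_map
    dm <- dm_tr
  }
  audit <- correlation_audit(X_train)
  tick("preprocess")

  # --- stability selection --------------------------------------------------
  scfg <- cfg$stability
  scfg$seed <- seed_stab
  stab <- tryCatch(
    run_stability(X_train, y_train, scfg, cfg$penalty, column_map = column_map),
    error = function(e)
      stop("pipeline aborted at stage 'stability' (replay with master_seed = ",
           cfg$master_seed, "): ", conditionMessage(e), call. = FALSE))
  tick("stability")

  # --- evaluation -----------------------------------------------------------
  refit <- NULL
  calib <- NULL
  if (length(stab$selected_columns)) {
    refit <- refit_selected(X_train, y_train, stab$selected_columns)
    calib <- calibrate(refit, X_test[, stab$selected_columns, drop = FALSE],
                       y_test, span = cfg$span)
  }
  tick("evaluation")

  # --- elastic-net sensitivity reruns --------------------------------------
  comparisons <- lapply(cfg$comparison_alphas, function(a) {
    pcfg <- cfg$penalty
    pcfg$alpha <- a
    st <- run_stability(X_train, y_train, scfg, pcfg, column_map = column_map)
    inter <- intersect(st$selected, stab$selected)
    uni <- union(st$selected, stab$selected)
    list(alpha = a, selected = st$selected,
         same_predictors = setequal(st$selected, stab$selected),
         jaccard = if (length(uni)) length(inter) / length(uni) else 1,
         lambda_mean = st$lambda_mean)
  })
  tick("comparison")

  manifest <- list(
    package_version = as.character(utils::packageVersion("aaostab")),
    master_seed = cfg$master_seed,
    derived_seeds = list(generate = seed_generate, missing = seed_missing,
                         split = seed_split, stability = seed_stab),
    cohort = if (!is.null(cfg$cohort)) list(
      source = "synthetic", n = cfg$cohort$n,
      n_predictors = length(cfg$cohort$predictors),
      intercept_log_age = cfg$cohort$intercept_log_age,
      noise_sd_log = cfg$cohort$noise_sd_log,
      missing_rate = cfg$cohort$missing_rate,
      era_fraction_pre_cutoff = cfg$cohort$era_fraction_pre_cutoff
    ) else list(source = cfg$cohort_csv),
    split_fraction = cfg$split_fraction,
    era_cutoff = cfg$era_cutoff,
    scaling = cfg$scaling,
    span = cfg$span,
    stability = unclass(scfg),
    penalty = unclass(cfg$penalty),
    comparison_alphas = cfg$comparison_alphas,
    analysis_n = n, n_train = length(split$train_idx),
    n_test = length(split$test_idx),
    correlation_range = c(audit$min_offdiag, audit$max_offdiag),
    selected = stab$selected
  )

  result <- structure(list(cohort_n = cohort_n, analysis_n = n, split = split,
                           design = dm, stability = stab, refit = refit,
                           calibration = calib, comparisons = comparisons,
                           manifest = manifest, timings = timings),
                      class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline(result, out_dir)
  result
}

.write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stability(result$stability, out_dir)
  if (!is.null(result$calibration)) write_calibration(result$calibration, out_dir)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  jsonlite::write_json(result$comparisons, file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(c(
    "analysis summary",
    sprintf("cohort rows: %d; complete analysed rows: %d (train %d / test %d)",
            result$cohort_n, result$analysis_n,
            length(result$split$train_idx), length(result$split$test_idx)),
    sprintf("selected predictors (%d): %s", length(result$stability$selected),
            paste(result$stability$selected, collapse = ", ")),
    sprintf("lambda: mean %.4g, s.d. %.4g", result$stability$lambda_mean,
            result$stability$lambda_sd),
    if (!is.null(result$calibration))
      sprintf("held-out: R^2 = %.3f, exp(MAE) = %.3f on n = %d",
              result$calibration$r_squared, result$calibration$exp_mae,
              result$calibration$n_test)
    else "held-out evaluation skipped: empty selection"
  ), file.path(out_dir, "summary.txt"))
  writeLines(sprintf("%s\t%.3f", names(result$timings),
                     unlist(result$timings)),
             file.path(out_dir, "timings.log"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", x$analysis_n, "analysed rows;",
      length(x$stability$selected), "selected predictors\n")
  print(x$stability)
  if (!is.null(x$calibration)) print(x$calibration)
  invisible(x)
}
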