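#' Refit the selected model by unpenalized least squares
#'
#' The stability-selected predictor set is refit at lambda = 0 (ordinary
#' least squares via the coordinate-descent solver) on the training design;
#' this fit generates the held-out predictions.  Modal coefficients remain a
#' descriptive summary; see [modal_model()] for the sensitivity-analysis
#' alternative that predicts with them directly.
#'
#' @param X_train Training design matrix.
#' @param y_train Log-scale outcome.
#' @param selected Nonempty character vector (or indices) of encoded columns.
#' @param tol Solver tolerance for the unpenalized refit (default 1e-10).
#' @return An `enet_fit` on the selected columns.
#' @export
refit_selected <- function(X_train, y_train, selected, tol = 1e-10) {
  if (length(selected) < 1L) stop("selected predictor set is empty", call. = FALSE)
  X_train <- as.matrix(X_train)
  Xs <- X_train[, selected, drop = FALSE]
  if (qr(cbind(1, Xs))$rank < ncol(Xs) + 1L)
    stop("selected design is rank deficient; cannot refit by least squares",
         call. = FALSE)
  fit_enet(Xs, y_train, lambda = 0,
           cfg = penalty_config(alpha = 1, tol = tol, max_sweeps = 1e6))
}

#' Predictive model from modal coefficients
#'
#' Builds an `enet_fit`-like object whose coefficients are the binned modal
#' coefficients of the selected encoded columns and whose intercept is the
#' binned mode of the per-resample intercepts, for sensitivity analyses of
#' the refit convention.
#'
#' @param result A `stability_result` with a nonempty selection.
#' @return An `enet_fit` usable with [predict.enet_fit()] on the selected
#'   columns.
#' @export
modal_model <- function(result) {
  stopifnot(inherits(result, "stability_result"))
  if (!length(result$selected_columns)) stop("no selected predictors", call. = FALSE)
  structure(list(
    intercept = modal_coefficient(result$intercept_draws,
                                  result$config$mode_bin_width),
    beta = result$modal_coef,
    lambda = NA_real_, alpha = result$penalty$alpha,
    n_sweeps = NA_integer_, converged = TRUE), class = "enet_fit")
}

#' Out-of-sample R squared
#'
#' `1 - SS_res / SS_tot` on the (log) scale supplied; can be negative on
#' held-out data.
#'
#' @param y_obs_log,y_pred_log Observed and predicted vectors (>= 2 values,
#'   observed variance > 0).
#' @return The coefficient of determination.
#' @export
r_squared <- function(y_obs_log, y_pred_log) {
  stopifnot(length(y_obs_log) == length(y_pred_log), length(y_obs_log) >= 2)
  sst <- sum((y_obs_log - mean(y_obs_log))^2)
  if (sst <= 0) stop("observed outcome has zero variance", call. = FALSE)
  1 - sum((y_obs_log - y_pred_log)^2) / sst
}

#' Exponentiated mean absolute error
#'
#' `exp(mean |y_obs_log - y_pred_log|)`: a multiplicative error factor on
#' the original (years) scale, 1 for perfect predictions.
#'
#' @param y_obs_log,y_pred_log Log-scale observed and predicted vectors.
#' @return The exponentiated MAE (>= 1).
#' @export
exp_mae <- function(y_obs_log, y_pred_log) {
  stopifnot(length(y_obs_log) == length(y_pred_log), length(y_obs_log) >= 1)
  exp(mean(abs(y_obs_log - y_pred_log)))
}

#' LOESS calibration curve with pointwise intervals
#'
#' Local linear regression with tricube weights over a span-fraction
#' neighbourhood (the classical LOESS smoother, computed exactly via
#' `stats::loess` with `degree = 1` and a direct surface), evaluated on the
#' sorted unique x values (thinned to at most 200 points), with pointwise
#' ~95% t-intervals from the local fit's standard errors.
#'
#' @param x,y Numeric vectors (n >= 5).
#' @param span Neighbourhood fraction in (0, 1].
#' @return Data frame with `predicted_log`, `smoothed`, `lower`, `upper`.
#' @export
loess_curve <- function(x, y, span = 0.3) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 5) stop("need >= 5 points", call. = FALSE)
  if (span <= 0 || span > 1) stop("span must be in (0,1]", call. = FALSE)
  if (ceiling(span * n) < 2) stop("span * n < 2: window too small", call. = FALSE)
  fit <- loess(y ~ x, span = span, degree = 1, family = "gaussian",
               control = loess.control(surface = "direct"))
  grid <- sort(unique(x))
  if (length(grid) > 200L)
    grid <- grid[unique(round(seq(1, length(grid), length.out = 200L)))]
  pr <- predict(fit, newdata = data.frame(x = grid), se = TRUE)
  tcrit <- qt(0.975, pr$df)
  data.frame(predicted_log = grid, smoothed = as.numeric(pr$fit),
             lower = as.numeric(pr$fit - tcrit * pr$se.fit),
             upper = as.numeric(pr$fit + tcrit * pr$se.fit))
}

#' Held-out calibration report
#'
#' Scores a fitted model on a held-out encoded test set: R squared, log-scale
#' MAE, exponentiated MAE, and a LOESS curve of observed against predicted
#' log outcomes (perfect calibration is the 45-degree line).
#'
#' @param fit An `enet_fit` (typically from [refit_selected()]).
#' @param X_test Encoded test design restricted to the fit's columns.
#' @param y_test_log Log-scale observed outcomes.
#' @param span LOESS span (default 0.3).
#' @return A `calibration_report`: `r_squared`, `mae_log`, `exp_mae`,
#'   `curve`, `span`, `n_test`, plus the raw `predicted_log`/`observed_log`.
#' @export
calibrate <- function(fit, X_test, y_test_log, span = 0.3) {
  X_test <- as.matrix(X_test)
  if (nrow(X_test) < 1L) stop("test set is empty", call. = FALSE)
  pred <- predict(fit, X_test)
  mae <- mean(abs(y_test_log - pred))
  structure(list(
    r_squared = r_squared(y_test_log, pred),
    mae_log = mae, exp_mae = exp(mae),
    curve = loess_curve(pred, y_test_log, span),
    span = span, n_test = nrow(X_test),
    predicted_log = pred, observed_log = y_test_log),
    class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("calibration_report: n_test =", x$n_test, "\n")
  cat(sprintf("  R^2 = %.3f | MAE(log) = %.4f | exp(MAE) = %.3f | span = %.2f\n",
              x$r_squared, x$mae_log, x$exp_mae, x$span))
  invisible(x)
}

#' Write a calibration report to disk
#'
#' @param report A `calibration_report`.
#' @param dir Output directory.
#' @return Invisibly, the written paths (JSON metrics, TSV curve).
#' @export
write_calibration <- function(report, dir) {
  stopifnot(inherits(report, "calibration_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_json <- file.path(dir, "calibration.json")
  jsonlite::write_json(list(
    r_squared = report$r_squared, mae_log = report$mae_log,
    exp_mae = report$exp_mae, span = report$span, n_test = report$n_test
  ), p_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  p_tsv <- file.path(dir, "calibration_curve.tsv")
  write.table(report$curve, p_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p_json, p_tsv))
}
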