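#' Stability-selection configuration
#'
#' @param B Number of bootstrap resamples (default 1000; analyses at desk
#'   scale typically use 200).
#' @param inclusion_threshold Strict inclusion-frequency cutoff in (0, 1);
#'   a predictor is selected when its frequency is strictly greater than
#'   this (default 0.90).
#' @param mode_bin_width Histogram bin width for the modal coefficient
#'   (default 0.001).
#' @param seed Master integer seed; all resampling and fold seeds derive
#'   from it.
#' @return A `stability_config` list.
#' @export
stability_config <- function(B = 1000, inclusion_threshold = 0.90,
                             mode_bin_width = 0.001, seed = 1L) {
  stopifnot(B >= 1, inclusion_threshold > 0, inclusion_threshold < 1,
            mode_bin_width > 0)
  structure(list(B = as.integer(B), inclusion_threshold = inclusion_threshold,
                 mode_bin_width = mode_bin_width, seed = as.integer(seed)),
            class = "stability_config")
}

#' Bootstrap index draw
#'
#' @param n Number of rows (>= 1).
#' @param seed Integer seed.
#' @return `n` indices drawn uniformly with replacement from `1..n`,
#'   deterministic given the seed.
#' @export
bootstrap_indices <- function(n, seed) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  sample.int(n, n, replace = TRUE)
}

#' Per-column inclusion frequencies
#'
#' @param coef_draws B x p matrix of coefficient draws (one row per
#'   resample).
#' @return Fraction of resamples in which each coefficient is exactly
#'   nonzero (the L1 solver produces exact zeros, which count as excluded).
#' @export
inclusion_frequency <- function(coef_draws) {
  coef_draws <- as.matrix(coef_draws)
  if (nrow(coef_draws) < 1L) stop("need >= 1 draw", call. = FALSE)
  colMeans(coef_draws != 0)
}

#' Strict threshold selection
#'
#' @param freq Named inclusion-frequency vector.
#' @param threshold Cutoff in (0, 1); selection is strict (`>`), so a
#'   frequency exactly at the threshold is not selected.
#' @return Names (or indices when unnamed) of the selected predictors.
#' @export
select_predictors <- function(freq, threshold = 0.90) {
  stopifnot(threshold > 0, threshold < 1)
  sel <- which(freq > threshold)
  if (!is.null(names(freq))) names(freq)[sel] else sel
}

#' Binned modal coefficient
#'
#' Histograms the draws into half-open bins of width `bin_width` anchored at
#' zero and returns the midpoint of the maximal-count bin.  Ties are broken
#' toward the bin nearest the median of the draws, then toward zero.
#'
#' @param draws Numeric vector of coefficient draws (>= 1).
#' @param bin_width Positive bin width (default 0.001).
#' @return The modal bin midpoint.
#' @export
modal_coefficient <- function(draws, bin_width = 0.001) {
  if (length(draws) < 1L) stop("empty draws", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  # tiny guard so a draw on a representable bin edge lands in its own bin
  idx <- floor(draws / bin_width + 1e-9)
  counts <- table(idx)
  cand <- as.numeric(names(counts)[counts == max(counts)])
  mid <- (cand + 0.5) * bin_width
  if (length(cand) > 1L) {
    med <- median(draws)
    d <- abs(mid - med)
    mid <- mid[d == min(d)]
    if (length(mid) > 1L) mid <- mid[abs(mid) == min(abs(mid))]
    mid <- mid[1L]
  }
  mid
}

# Deterministic sub-seeds below 2^31 derived from a master seed.
.derive_seeds <- function(master, k) {
  set.seed(as.integer(master))
  matrix(sample.int(2147483646L, 2L * k, replace = TRUE), ncol = 2L,
         dimnames = list(NULL, c("resample", "fold")))
}

#' Bootstrap stability selection around cross-validated penalized fits
#'
#' For each of B resamples: draw n rows with replacement from the training
#' design, run K-fold cross-validation on the resample to locate the
#' MSE-minimizing lambda, and record the resample's full-data coefficients at
#' that lambda.  Afterwards, rank predictors by the fraction of resamples in
#' which their coefficient was nonzero, select those strictly above the
#' inclusion threshold, and report each selected predictor's binned modal
#' coefficient together with the mean and s.d. of the per-resample optimal
#' lambdas.
#'
#' A resample on which cross-validation fails (degenerate fold) is logged and
#' re-drawn with a fresh derived seed; if more than 1% of resamples are
#' degenerate the run aborts.
#'
#' @param X_train Complete numeric training design (rows >= `pcfg$K`).
#' @param y_train Log-scale outcome vector.
#' @param scfg A [stability_config()].
#' @param pcfg A [penalty_config()].
#' @param column_map Optional `column_map` from [encode()]; when given,
#'   frequencies are also aggregated to source predictors (a predictor counts
#'   as included when any of its encoded columns is nonzero) and selection is
#'   reported at the predictor level.
#' @return A `stability_result`: `coef_draws` (B x p), `intercept_draws`,
#'   `inclusion_freq` (encoded columns), `predictor_freq`, `selected`
#'   (source predictors), `selected_columns`, `modal_coef` (per selected
#'   encoded column), `lambda_draws`, `lambda_mean`, `lambda_sd`,
#'   `n_degenerate`, and the configs.
#' @export
run_stability <- function(X_train, y_train, scfg = stability_config(),
                          pcfg = penalty_config(), column_map = NULL) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (n < pcfg$K) stop("need at least K rows", call. = FALSE)
  if (anyNA(X_train)) stop("X_train must be complete", call. = FALSE)
  B <- scfg$B
  n_spare <- max(5L, as.integer(ceiling(0.02 * B)))
  seeds <- .derive_seeds(scfg$seed, B + n_spare)
  p <- ncol(X_train)
  coef_draws <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(X_train)))
  intercept_draws <- numeric(B)
  lambda_draws <- numeric(B)
  n_degenerate <- 0L
  next_spare <- B
  for (b in seq_len(B)) {
    srow <- b
    repeat {
      res <- tryCatch({
        idx <- bootstrap_indices(n, seeds[srow, "resample"])
        cv <- cv_select(X_train[idx, , drop = FALSE], y_train[idx], pcfg,
                        seed = seeds[srow, "fold"])
        list(beta = cv$fit$beta[, cv$index_min],
             intercept = cv$fit$intercepts[cv$index_min],
             lambda = cv$lambda_min)
      }, error = function(e) e)
      if (!inherits(res, "error")) break
      n_degenerate <- n_degenerate + 1L
      if (n_degenerate > max(1, 0.01 * B))
        stop("more than 1% of resamples degenerate; last error: ",
             conditionMessage(res), call. = FALSE)
      next_spare <- next_spare + 1L
      if (next_spare > nrow(seeds))
        stop("exhausted spare seeds after repeated degenerate resamples",
             call. = FALSE)
      srow <- next_spare
    }
    coef_draws[b, ] <- res$beta
    intercept_draws[b] <- res$intercept
    lambda_draws[b] <- res$lambda
  }
  freq <- inclusion_frequency(coef_draws)
  # selection operates on encoded columns: under a groupless L1 penalty each
  # dummy carries its own coefficient, so "included" is a per-coefficient
  # event; a categorical predictor is selected when any of its levels clears
  # the threshold on its own
  sel_cols <- select_predictors(freq, scfg$inclusion_threshold)
  if (!is.null(column_map)) {
    sources <- unique(column_map$source)
    # informational per-source frequency: any encoded column nonzero
    pfreq <- vapply(sources, function(s) {
      cols <- column_map$column[column_map$source == s]
      mean(apply(coef_draws[, cols, drop = FALSE] != 0, 1L, any))
    }, numeric(1))
    names(pfreq) <- sources
    selected <- unique(column_map$source[match(sel_cols, column_map$column)])
  } else {
    pfreq <- freq
    selected <- sel_cols
  }
  modal <- vapply(sel_cols, function(cn)
    modal_coefficient(coef_draws[, cn], scfg$mode_bin_width), numeric(1))
  structure(list(coef_draws = coef_draws, intercept_draws = intercept_draws,
                 inclusion_freq = freq, predictor_freq = pfreq,
                 selected = selected, selected_columns = sel_cols,
                 modal_coef = modal,
                 lambda_draws = lambda_draws,
                 lambda_mean = mean(lambda_draws),
                 lambda_sd = sd(lambda_draws),
                 n_degenerate = n_degenerate,
                 config = scfg, penalty = pcfg,
                 column_map = column_map),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("stability_result:", nrow(x$coef_draws), "resamples x",
      ncol(x$coef_draws), "encoded columns\n")
  cat("  selected (freq >", x$config$inclusion_threshold, "):",
      length(x$selected), "predictors\n")
  if (length(x$modal_coef)) {
    df <- data.frame(column = names(x$modal_coef),
                     inclusion_freq = round(x$inclusion_freq[names(x$modal_coef)], 3),
                     modal_coef = x$modal_coef, row.names = NULL)
    print(df[order(df$modal_coef), ])
  }
  cat("  lambda: mean =", signif(x$lambda_mean, 4),
      " s.d. =", signif(x$lambda_sd, 4), "\n")
  invisible(x)
}

#' Export a stability result as plain-text files
#'
#' Writes the B x p coefficient draws (CSV), a per-predictor summary table
#' (CSV: inclusion frequency, selected flag, modal coefficient), a JSON
#' summary (lambda mean/s.d., config echo), and kernel-density curves of the
#' selected predictors' coefficient draws (TSV) for density-plot style
#' displays.
#'
#' @param result A `stability_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_stability <- function(result, dir) {
  stopifnot(inherits(result, "stability_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_draws <- file.path(dir, "stability_coef_draws.csv")
  write.csv(as.data.frame(result$coef_draws), p_draws, row.names = FALSE)
  cols <- colnames(result$coef_draws)
  summ <- data.frame(
    column = cols,
    inclusion_freq = as.numeric(result$inclusion_freq[cols]),
    selected = cols %in% result$selected_columns,
    modal_coef = ifelse(cols %in% names(result$modal_coef),
                        result$modal_coef[cols], NA_real_))
  p_sum <- file.path(dir, "stability_summary.csv")
  write.csv(summ, p_sum, row.names = FALSE)
  p_json <- file.path(dir, "stability_summary.json")
  jsonlite::write_json(list(
    lambda_mean = result$lambda_mean, lambda_sd = result$lambda_sd,
    n_resamples = nrow(result$coef_draws),
    n_degenerate = result$n_degenerate,
    selected = as.list(result$selected),
    config = unclass(result$config),
    penalty = unclass(result$penalty)
  ), p_json, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  p_dens <- file.path(dir, "stability_density.tsv")
  dens <- do.call(rbind, lapply(result$selected_columns, function(cn) {
    d <- density(result$coef_draws[, cn])
    data.frame(column = cn, x = d$x, density = d$y)
  }))
  if (is.null(dens))
    dens <- data.frame(column = character(0), x = numeric(0), density = numeric(0))
  write.table(dens, p_dens, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p_draws, p_sum, p_json, p_dens))
}
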