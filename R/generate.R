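#' Generate a synthetic cohort table
#'
#' Draws correlated mixed-type predictors through a Gaussian copula: latent
#' standard-normal vectors with the spec's `latent_correlation` are transformed
#' marginally to each predictor's declared kind (binary by prevalence
#' threshold, categorical by level-weight quantile cut-points — equiprobable by
#' default —, numeric kept standard Gaussian).  The outcome is
#' `aao_years = exp(intercept_log_age + sum_j true_effect_j * encoded_j + eps)`
#' with `eps ~ Normal(0, noise_sd_log)`, hence always positive.  A collection
#' year (`era`) is drawn in 2002–2007 with probability
#' `era_fraction_pre_cutoff`, otherwise in 2008–2015.  No missingness is
#' applied here; see [inject_missingness()].
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the table is deterministic given `(spec, seed)`.
#' @return A `cohort_table`: a data frame with columns `aao_years`, `era`, and
#'   one column per predictor, carrying the spec as attribute `"schema"`.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  n <- spec$n
  preds <- spec$predictors
  p <- length(preds)
  L <- chol(spec$latent_correlation + diag(1e-10, p))
  Z <- matrix(rnorm(n * p), n, p) %*% L
  U <- pnorm(Z)

  cols <- vector("list", p)
  enc_contrib <- numeric(n)  # running sum of true_effect_j * encoded_j
  for (j in seq_len(p)) {
    ps <- preds[[j]]
    if (ps$kind == "binary") {
      x <- as.integer(U[, j] > 1 - ps$prevalence)
      enc_contrib <- enc_contrib + ps$true_effect * x
    } else if (ps$kind == "numeric") {
      x <- Z[, j]
      enc_contrib <- enc_contrib + ps$true_effect * x
    } else {
      w <- ps$level_weights
      if (is.null(w)) w <- rep(1 / length(ps$levels), length(ps$levels))
      br <- c(0, cumsum(w))
      br[length(br)] <- 1
      idx <- findInterval(U[, j], br, rightmost.closed = TRUE,
                          all.inside = TRUE)
      x <- factor(ps$levels[idx], levels = ps$levels)
      for (k in seq_along(ps$true_effect)) {
        enc_contrib <- enc_contrib +
          ps$true_effect[k] * as.numeric(x == ps$levels[k + 1L])
      }
    }
    cols[[j]] <- x
  }
  names(cols) <- vapply(preds, `[[`, character(1), "name")

  y_log <- spec$intercept_log_age + enc_contrib + rnorm(n, 0, spec$noise_sd_log)
  aao <- exp(y_log)
  pre <- runif(n) < spec$era_fraction_pre_cutoff
  era <- ifelse(pre, sample(2002:2007, n, replace = TRUE),
                sample(2008:2015, n, replace = TRUE))

  tab <- data.frame(aao_years = aao, era = as.integer(era), cols,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (spec$truncate_aao_65) tab <- tab[tab$aao_years < 65, , drop = FALSE]
  rownames(tab) <- NULL
  as_cohort_table(tab, spec)
}

as_cohort_table <- function(df, spec) {
  structure(df, schema = spec, class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x), "participants x", ncol(x) - 2L, "predictors",
      "(+ aao_years, era)\n")
  miss <- sum(is.na(x[, setdiff(names(x), c("aao_years", "era")), drop = FALSE]))
  if (miss > 0) cat("  missing predictor cells:", miss, "\n")
  print(head(as.data.frame(x), 4L))
  invisible(x)
}

#' Set predictor cells missing completely at random
#'
#' Each predictor cell is independently set to `NA` with probability `rate`
#' (MCAR); the outcome and era columns are never touched.
#'
#' @param table A `cohort_table`.
#' @param rate Missingness probability in [0, 1).
#' @param seed Integer seed; deterministic given `(table, rate, seed)`.
#' @return The table with missing cells injected.
#' @export
inject_missingness <- function(table, rate, seed) {
  stopifnot(inherits(table, "cohort_table"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0,1)", call. = FALSE)
  if (rate == 0) return(table)
  set.seed(as.integer(seed))
  pred_cols <- setdiff(names(table), c("aao_years", "era"))
  n <- nrow(table)
  for (cn in pred_cols) {
    hit <- runif(n) < rate
    table[[cn]][hit] <- NA
  }
  table
}

#' Write / read a cohort table as CSV plus a JSON schema sidecar
#'
#' The CSV holds the data (missing cells as empty fields); the sidecar
#' declares each predictor's kind, levels and prevalence so the table can be
#' reconstructed with correct types.
#'
#' @param table A `cohort_table`.
#' @param csv_path,schema_path Output paths.
#' @return `write_cohort()` invisibly returns the paths; `read_cohort()`
#'   returns a `cohort_table`.
#' @export
write_cohort <- function(table, csv_path, schema_path) {
  stopifnot(inherits(table, "cohort_table"))
  spec <- attr(table, "schema")
  write.csv(as.data.frame(table), csv_path, row.names = FALSE, na = "")
  schema <- list(
    outcome = "aao_years", era = "era",
    n = nrow(table),
    intercept_log_age = spec$intercept_log_age,
    noise_sd_log = spec$noise_sd_log,
    predictors = lapply(spec$predictors, function(p) {
      list(name = p$name, kind = p$kind, levels = p$levels,
           prevalence = p$prevalence, block = p$block,
           true_effect = p$true_effect)
    })
  )
  jsonlite::write_json(schema, schema_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(csv = csv_path, schema = schema_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(csv_path, schema_path) {
  if (!file.exists(schema_path))
    stop("schema sidecar not found: expected a JSON schema at '",
         schema_path, "'", call. = FALSE)
  schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  df <- read.csv(csv_path, stringsAsFactors = FALSE,
                 na.strings = "", check.names = FALSE)
  preds <- lapply(schema$predictors, function(p) {
    predictor_spec(p$name, p$kind,
                   levels = if (length(p$levels)) unlist(p$levels) else NULL,
                   prevalence = p$prevalence,
                   block = p$block,
                   true_effect = if (length(p$true_effect)) unlist(p$true_effect) else 0)
  })
  for (p in preds) {
    if (p$kind == "categorical") {
      df[[p$name]] <- factor(df[[p$name]], levels = p$levels)
    } else if (p$kind == "binary") {
      df[[p$name]] <- as.integer(df[[p$name]])
    }
  }
  spec <- cohort_spec(
    n = nrow(df), predictors = preds,
    intercept_log_age = schema$intercept_log_age %||% 3.1,
    noise_sd_log = schema$noise_sd_log %||% 0.35
  )
  as_cohort_table(df, spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
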