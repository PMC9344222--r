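#' Complete-case filtering (listwise deletion)
#'
#' Drops every row with a missing value in the outcome or any predictor
#' column, preserving row order.
#'
#' @param table A `cohort_table` with at least one row.
#' @return The complete-case table, with attribute `"n_removed"` recording the
#'   number of rows dropped.  If no complete rows remain an empty table is
#'   returned with a warning.
#' @export
listwise_delete <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  if (nrow(table) < 1L) stop("table has no rows", call. = FALSE)
  cols <- setdiff(names(table), "era")
  keep <- complete.cases(as.data.frame(table)[, cols, drop = FALSE])
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "schema") <- attr(table, "schema")
  class(out) <- class(table)
  attr(out, "n_removed") <- sum(!keep)
  if (nrow(out) == 0L) warning("listwise deletion removed every row", call. = FALSE)
  out
}

#' Drop rows collected before an era cutoff
#'
#' @param table A `cohort_table` with an `era` column (collection year).
#' @param cutoff Numeric cutoff year (default 2008); rows with `era < cutoff`
#'   are removed.  Idempotent.
#' @return The filtered table.
#' @export
filter_era <- function(table, cutoff = 2008) {
  stopifnot(inherits(table, "cohort_table"))
  if (!"era" %in% names(table)) stop("era column missing", call. = FALSE)
  keep <- table$era >= cutoff
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "schema") <- attr(table, "schema")
  class(out) <- class(table)
  if (nrow(out) == 0L) warning("era filter removed every row", call. = FALSE)
  out
}

#' Natural-log transform of the positive outcome
#'
#' @param table A `cohort_table` whose `aao_years` are all positive.
#' @return Numeric vector `log(aao_years)`.
#' @export
log_transform_outcome <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  y <- table$aao_years
  bad <- which(!is.na(y) & y <= 0)
  if (length(bad))
    stop("non-positive age at onset in rows: ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  log(y)
}

#' Encode a cohort table as a numeric design matrix
#'
#' Binary predictors become single 0/1 columns (left unscaled); categorical
#' predictors become K-1 dummy indicator columns against the first schema
#' level as reference; numeric predictors are z-standardised with mean and
#' s.d. (denominator n-1) of the rows provided, or with previously recorded
#' `scaling_params` when transforming new data with a training-fit encoding.
#'
#' @param table A complete `cohort_table` (run [listwise_delete()] first).
#' @param scaling_params Optional `scaling_params` data frame from a previous
#'   `encode()` call, to reuse training means/s.d.s on new rows.
#' @return A `design_matrix` list: `X` (n x p numeric matrix), `y_log`,
#'   `column_map` (data frame mapping each encoded column to its source
#'   predictor, level and encoding kind), `scaling_params`.
#' @export
encode <- function(table, scaling_params = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  spec <- attr(table, "schema")
  if (anyNA(as.data.frame(table)[, setdiff(names(table), "era"), drop = FALSE]))
    stop("table has missing values; run listwise_delete() first", call. = FALSE)
  y_log <- log_transform_outcome(table)
  cols <- list()
  map <- list()
  sp <- list()
  for (ps in spec$predictors) {
    x <- table[[ps$name]]
    if (ps$kind == "binary") {
      v <- as.numeric(x)
      if (!all(v %in% c(0, 1)))
        stop("binary predictor '", ps$name, "' has values outside {0,1}", call. = FALSE)
      cols[[ps$name]] <- v
      map[[length(map) + 1L]] <- data.frame(column = ps$name, source = ps$name,
                                            level = NA_character_, kind = "binary")
    } else if (ps$kind == "numeric") {
      v <- as.numeric(x)
      if (!is.null(scaling_params)) {
        row <- scaling_params[scaling_params$column == ps$name, ]
        if (nrow(row) != 1L)
          stop("no recorded scaling for numeric column '", ps$name, "'", call. = FALSE)
        m <- row$mean; s <- row$sd
      } else {
        m <- mean(v); s <- sd(v)
        if (!is.finite(s) || s == 0)
          stop("numeric predictor '", ps$name, "' has zero variance", call. = FALSE)
      }
      cols[[ps$name]] <- (v - m) / s
      sp[[length(sp) + 1L]] <- data.frame(column = ps$name, mean = m, sd = s)
      map[[length(map) + 1L]] <- data.frame(column = ps$name, source = ps$name,
                                            level = NA_character_, kind = "numeric")
    } else {
      x <- as.character(x)
      unseen <- setdiff(unique(x), ps$levels)
      if (length(unseen))
        stop("unseen level(s) in '", ps$name, "': ",
             paste(unseen, collapse = ", "), call. = FALSE)
      for (lev in ps$levels[-1L]) {
        cn <- paste(ps$name, lev, sep = ".")
        cols[[cn]] <- as.numeric(x == lev)
        map[[length(map) + 1L]] <- data.frame(column = cn, source = ps$name,
                                              level = lev, kind = "dummy")
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(
    X = X, y_log = y_log,
    column_map = do.call(rbind, map),
    scaling_params = if (length(sp)) do.call(rbind, sp) else
      data.frame(column = character(0), mean = numeric(0), sd = numeric(0))
  ), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design_matrix:", nrow(x$X), "rows x", ncol(x$X), "encoded columns\n")
  cat("  kinds:", paste(names(table(x$column_map$kind)),
                        table(x$column_map$kind), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Random train/test partition
#'
#' @param n_rows Number of rows (>= 2).
#' @param fraction Training fraction in (0, 1); the training size is
#'   `round(fraction * n_rows)` under R's round-half-even rule.
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @return A `split_indices` list with sorted `train_idx`, `test_idx`,
#'   `fraction` and `seed`.
#' @export
split_cohort <- function(n_rows, fraction = 0.7, seed) {
  stopifnot(n_rows >= 2, fraction > 0, fraction < 1)
  n_train <- round(fraction * n_rows)
  if (n_train < 1 || n_train > n_rows - 1)
    stop("degenerate split: train size ", n_train, " of ", n_rows, call. = FALSE)
  set.seed(as.integer(seed))
  tr <- sort(sample.int(n_rows, n_train))
  structure(list(train_idx = tr, test_idx = setdiff(seq_len(n_rows), tr),
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_indices")
}

#' Pairwise Pearson correlation audit of an encoded design
#'
#' @param design A `design_matrix` (or bare numeric matrix) with >= 3 rows.
#' @return List: `matrix` (p x p Pearson correlations, `NA` for zero-variance
#'   columns), `min_offdiag`, `max_offdiag` (over defined entries), and
#'   `undefined_columns`.
#' @export
correlation_audit <- function(design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (nrow(X) < 3L) stop("need >= 3 rows", call. = FALSE)
  sds <- apply(X, 2L, sd)
  bad <- colnames(X)[sds == 0]
  suppressWarnings(R <- cor(X))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R)[sds > 0] <- 1
  off <- R[upper.tri(R)]
  off <- off[!is.na(off)]
  list(matrix = R,
       min_offdiag = if (length(off)) min(off) else NA_real_,
       max_offdiag = if (length(off)) max(off) else NA_real_,
       undefined_columns = bad)
}
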