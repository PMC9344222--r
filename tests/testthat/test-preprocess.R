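make_small_cohort <- function(n = 10, seed = 1) {
  spec <- cohort_spec(n, list(
    predictor_spec("b", "binary", prevalence = 0.4),
    predictor_spec("z", "numeric")))
  generate_cohort(spec, seed = seed)
}

test_that("listwise deletion keeps exactly the complete rows in order", {
  co <- make_small_cohort(10)
  co$b[c(3, 7)] <- NA
  out <- listwise_delete(co)
  expect_equal(nrow(out), 8L)
  expect_equal(attr(out, "n_removed"), 2L)
  expect_equal(out$aao_years, co$aao_years[-c(3, 7)])
  full <- make_small_cohort(10)
  expect_equal(as.data.frame(listwise_delete(full)), as.data.frame(full),
               ignore_attr = TRUE)
  allna <- make_small_cohort(4)
  allna$z <- NA_real_
  expect_warning(empty <- listwise_delete(allna), "every row")
  expect_equal(nrow(empty), 0L)
})

test_that("MCAR survival after listwise deletion matches independence", {
  spec <- default_cohort_spec(n = 1000)
  co <- inject_missingness(generate_cohort(spec, seed = 2), 0.1, seed = 3)
  out <- listwise_delete(co)
  # P(row complete) = 0.9^28 over 28 independently-missing predictors
  p <- 0.9^28
  expect_lt(abs(nrow(out) - 1000 * p), 3 * sqrt(1000 * p * (1 - p)))
})

test_that("era filter drops pre-cutoff rows and is idempotent", {
  co <- make_small_cohort(20, seed = 4)
  co$era <- rep(c(2005L, 2010L), 10)
  out <- filter_era(co, 2008)
  expect_equal(nrow(out), 10L)
  expect_true(all(out$era >= 2008))
  expect_equal(as.data.frame(filter_era(out, 2008)), as.data.frame(out))
  expect_warning(filter_era(co, 2020), "every row")
  co$era <- NULL
  expect_error(filter_era(co), "era column")
})

test_that("log transform is the natural log and rejects non-positive ages", {
  co <- make_small_cohort(3, seed = 5)
  co$aao_years <- c(1, exp(2), 23.0)
  expect_equal(log_transform_outcome(co), c(0, 2, 3.1354942159291497),
               tolerance = 1e-12)
  co$aao_years[2] <- -1
  expect_error(log_transform_outcome(co), "rows: 2")
})

test_that("encoding follows K-1 dummies, z-scores and untouched binaries", {
  spec <- cohort_spec(3, list(
    predictor_spec("b", "binary", prevalence = 0.5),
    predictor_spec("cat", "categorical", levels = c("A", "B", "C")),
    predictor_spec("z", "numeric")))
  df <- data.frame(aao_years = c(10, 20, 30), era = 2010L,
                   b = c(0L, 1L, 1L),
                   cat = factor(c("A", "B", "C"), levels = c("A", "B", "C")),
                   z = c(1, 2, 3))
  co <- aaostab:::as_cohort_table(df, spec)
  dm <- encode(co)
  expect_identical(colnames(dm$X), c("b", "cat.B", "cat.C", "z"))
  expect_equal(dm$X[, "b"], c(0, 1, 1))          # binary passes through
  expect_equal(dm$X[, "cat.B"], c(0, 1, 0))      # reference level = A
  expect_equal(dm$X[, "cat.C"], c(0, 0, 1))
  expect_equal(dm$X[, "z"], c(-1, 0, 1))         # sd with denominator n-1
  expect_equal(dm$scaling_params$mean, 2)
  expect_equal(dm$scaling_params$sd, 1)
  # column_map inverts every encoded column to its source
  expect_identical(dm$column_map$source, c("b", "cat", "cat", "z"))
  expect_identical(dm$column_map$level, c(NA, "B", "C", NA))
})

test_that("encoding errors on zero variance, unseen levels and missing cells", {
  spec <- cohort_spec(3, list(predictor_spec("z", "numeric")))
  df <- data.frame(aao_years = c(10, 20, 30), era = 2010L, z = c(1, 1, 1))
  co <- aaostab:::as_cohort_table(df, spec)
  expect_error(encode(co), "zero variance")
  spec2 <- cohort_spec(3, list(
    predictor_spec("cat", "categorical", levels = c("A", "B"))))
  df2 <- data.frame(aao_years = c(10, 20, 30), era = 2010L,
                    cat = c("A", "B", "Q"))
  co2 <- aaostab:::as_cohort_table(df2, spec2)
  expect_error(encode(co2), "unseen level")
  co3 <- make_small_cohort(5)
  co3$z[2] <- NA
  expect_error(encode(co3), "missing values")
})

test_that("recorded scaling parameters reproduce the training encoding", {
  spec <- default_cohort_spec(n = 120)
  co <- generate_cohort(spec, seed = 6)
  dm <- encode(co)
  again <- encode(co, scaling_params = dm$scaling_params)
  expect_equal(again$X, dm$X, tolerance = 1e-12)
})

test_that("split sizes follow round-half-even and partition the rows", {
  sp <- split_cohort(10, 0.7, seed = 1)
  expect_length(sp$train_idx, 7L)
  expect_length(sp$test_idx, 3L)
  # 0.7 * 1022 = 715.4 -> 715/307, not the historical 717/305
  sp2 <- split_cohort(1022, 0.7, seed = 2)
  expect_length(sp2$train_idx, 715L)
  expect_length(sp2$test_idx, 307L)
  expect_identical(split_cohort(50, 0.7, seed = 9)$train_idx,
                   split_cohort(50, 0.7, seed = 9)$train_idx)
  for (s in 1:1000) {
    sp <- split_cohort(37, 0.7, seed = s)
    expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
    expect_identical(sort(c(sp$train_idx, sp$test_idx)), 1:37)
  }
  expect_error(split_cohort(2, 0.1, seed = 1), "degenerate")
})

test_that("correlation audit reports extremes and flags zero variance", {
  X <- cbind(a = 1:10, b = 1:10, c = rnorm(10))
  aud <- correlation_audit(X)
  expect_equal(aud$matrix["a", "b"], 1)
  Xz <- cbind(a = rnorm(10), z = rep(2, 10))
  audz <- correlation_audit(Xz)
  expect_true(is.na(audz$matrix["a", "z"]))
  expect_identical(audz$undefined_columns, "z")
  co <- generate_cohort(two_numeric_spec(5000, 0.68), seed = 7)
  aud68 <- correlation_audit(encode(co)$X)
  expect_lt(abs(aud68$max_offdiag - 0.68), 0.05)
})
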