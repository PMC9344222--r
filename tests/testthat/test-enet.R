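test_that("soft thresholding shrinks toward the dead zone", {
  cases <- list(c(3, 1, 2), c(-0.5, 1, 0), c(-3, 1, -2), c(0, 0, 0),
                c(2, 0, 2), c(1, 1, 0))
  for (cs in cases) expect_equal(soft_threshold(cs[1], cs[2]), cs[3])
  expect_equal(soft_threshold(c(3, -3), 1), c(2, -2))
  expect_error(soft_threshold(1, -0.1), "gamma")
})

test_that("lambda_max is the exact all-zero boundary", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  lm_ <- lambda_max(X, y, alpha = 1)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  expect_equal(lm_, max(abs(crossprod(Xc, yc))) / 20)
  fit_above <- fit_enet(X, y, 1.001 * lm_)
  expect_true(all(fit_above$beta == 0))
  fit_below <- fit_enet(X, y, 0.9 * lm_)
  expect_gt(sum(fit_below$beta != 0), 0)
  expect_equal(lambda_max(X, rep(2, 20)), 0)
  expect_error(lambda_max(X, y, alpha = 0), "ridge")
})

test_that("at or above lambda_max the fit is the null model", {
  for (s in 1:5) {
    inst <- random_instance(s)
    lmax <- lambda_max(inst$X, inst$y)
    fit <- fit_enet(inst$X, inst$y, lmax)
    expect_identical(unname(fit$beta), rep(0, inst$p))
    expect_equal(fit$intercept, mean(inst$y))
  }
})

test_that("lambda = 0 reproduces ordinary least squares", {
  for (s in 1:10) {
    inst <- random_instance(s)
    fit <- fit_enet(inst$X, inst$y, 0,
                    cfg = penalty_config(tol = 1e-12, max_sweeps = 1e6))
    ols <- lm.fit(cbind(1, inst$X), inst$y)$coefficients
    expect_lt(max(abs(c(fit$intercept, fit$beta) - ols)), 1e-6)
  }
})

test_that("alpha = 0 matches the closed-form ridge solution", {
  for (s in 1:10) {
    inst <- random_instance(s)
    lam <- 0.3
    fit <- fit_enet(inst$X, inst$y, lam,
                    cfg = penalty_config(alpha = 0, tol = 1e-12,
                                         max_sweeps = 1e6))
    oracle <- ridge_closed_form(inst$X, inst$y, lam)
    expect_lt(max(abs(fit$beta - oracle$beta)), 1e-6)
    expect_lt(abs(fit$intercept - oracle$intercept), 1e-6)
  }
})

test_that("the objective is continuous in alpha near the LASSO end", {
  inst <- random_instance(3)
  lam <- 0.5 * lambda_max(inst$X, inst$y)
  f1 <- fit_enet(inst$X, inst$y, lam, penalty_config(alpha = 1, tol = 1e-10))
  f2 <- fit_enet(inst$X, inst$y, lam,
                 penalty_config(alpha = 0.999999, tol = 1e-10))
  expect_lt(max(abs(f1$beta - f2$beta)), 1e-4)
})

test_that("coordinate descent matches the FISTA oracle and glmnet", {
  skip_if_not_installed("glmnet")
  for (s in 1:8) {
    inst <- random_instance(s)
    for (alpha in c(1, 0.5)) {
      lam <- 0.2 * lambda_max(inst$X, inst$y, max(alpha, 0.5))
      fit <- fit_enet(inst$X, inst$y, lam,
                      penalty_config(alpha = alpha, tol = 1e-11))
      orc <- fista_enet(inst$X, inst$y, lam, alpha)
      o_cd <- obj_value(inst$X, inst$y, fit$intercept, fit$beta, lam, alpha)
      o_or <- obj_value(inst$X, inst$y, orc$intercept, orc$beta, lam, alpha)
      expect_lt(o_cd - o_or, 1e-7)  # CD should be no worse than the oracle
      expect_lt(abs(o_cd - o_or), 1e-5)
      # glmnet standardizes y internally, which rescales the ridge part of
      # the penalty by sd_n(y); map (lambda, alpha) onto glmnet's scale so
      # both solvers face the identical objective
      sdn <- sqrt(mean((inst$y - mean(inst$y))^2))
      lam_g <- lam * alpha + lam * (1 - alpha) * sdn
      alpha_g <- lam * alpha / lam_g
      g <- glmnet::glmnet(inst$X, inst$y, alpha = alpha_g,
                          standardize = FALSE, thresh = 1e-14)
      cb <- as.numeric(coef(g, s = lam_g, exact = TRUE, x = inst$X,
                            y = inst$y, alpha = alpha_g))[-1]
      expect_lt(max(abs(cb - fit$beta)), 1e-4)
    }
  }
})

test_that("warm-started path solutions equal cold starts and begin null", {
  inst <- random_instance(11, n_max = 60)
  cfg <- penalty_config(n_lambda = 40, tol = 1e-10)
  path <- fit_path(inst$X, inst$y, cfg)
  expect_true(all(path$beta[, 1] == 0))
  expect_equal(diff(path$lambdas) < 0, rep(TRUE, 39))
  for (l in c(5, 20, 40)) {
    cold <- fit_enet(inst$X, inst$y, path$lambdas[l], cfg)
    expect_lt(max(abs(cold$beta - path$beta[, l])), 1e-6)
  }
  single <- fit_path(inst$X, inst$y, penalty_config(n_lambda = 1))
  expect_length(single$lambdas, 1L)
  expect_equal(single$lambdas, lambda_max(inst$X, inst$y))
})

test_that("KKT certificate holds for converged fits", {
  for (s in 1:20) {
    inst <- random_instance(s + 100)
    lam <- runif(1, 0.05, 0.8) * lambda_max(inst$X, inst$y)
    alpha <- sample(c(1, 0.7, 0.3), 1)
    fit <- fit_enet(inst$X, inst$y, lam,
                    penalty_config(alpha = alpha, tol = 1e-11))
    chk <- kkt_check(fit, inst$X, inst$y, tol = 1e-6)
    expect_true(chk$ok)
  }
})

test_that("cross-validation selects lambda by held-fold MSE", {
  # noiseless exactly-linear data: the smallest grid lambda wins and the
  # minimum CV error vanishes with the penalty
  set.seed(42)
  X <- matrix(rnorm(200), 50, 4)
  y <- 2 + as.numeric(X %*% c(1, -1, 0.5, 0))
  cv <- cv_select(X, y, penalty_config(n_lambda = 60, lambda_min_ratio = 1e-6),
                  seed = 1)
  expect_equal(cv$lambda_min, min(cv$lambdas))
  expect_lt(min(cv$cv_mse), 1e-6)
  expect_equal(cv$cv_mse[cv$index_min], min(cv$cv_mse))
  # determinism of the fold assignment
  cv2 <- cv_select(X, y, penalty_config(n_lambda = 60,
                                        lambda_min_ratio = 1e-6), seed = 1)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_identical(cv$cv_mse, cv2$cv_mse)
  expect_error(cv_select(X[1:5, ], y[1:5], penalty_config(K = 10), seed = 1),
               "exceed")
})

test_that("leave-one-out CV equals the brute-force oracle on a toy", {
  set.seed(7)
  X <- matrix(rnorm(10), 5, 2)
  y <- c(1.2, -0.4, 0.8, 2.1, 0.3)
  cfg <- penalty_config(K = 5, n_lambda = 12, tol = 1e-11)
  cv <- cv_select(X, y, cfg, seed = 3)
  # brute force: for each left-out row, path-fit the rest on the same grid
  errs <- matrix(NA_real_, 5, 12)
  for (i in 1:5) {
    k <- cv$fold_assignment[i]
    pk <- fit_path(X[-i, , drop = FALSE], y[-i], cfg, lambdas = cv$lambdas)
    errs[k, ] <- (y[i] - (pk$intercepts + X[i, ] %*% pk$beta))^2
  }
  expect_equal(cv$cv_mse, colMeans(errs), tolerance = 1e-9)
})

test_that("on pure noise the selected model behaves like the null", {
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(200 * 10), 200, 10)
    y <- rnorm(200)
    cv <- cv_select(X, y, penalty_config(n_lambda = 50), seed = s)
    if (abs(cv$cv_mse[cv$index_min] - var(y)) < 0.1 * var(y)) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("prediction is the affine map and validates columns", {
  inst <- random_instance(5)
  colnames(inst$X) <- paste0("v", seq_len(inst$p))
  lmax <- lambda_max(inst$X, inst$y)
  null_fit <- fit_enet(inst$X, inst$y, lmax)
  expect_equal(predict(null_fit, inst$X),
               rep(mean(inst$y), inst$n))
  fit <- fit_enet(inst$X, inst$y, 0.1 * lmax)
  expect_equal(predict(fit, inst$X),
               as.numeric(fit$intercept + inst$X %*% fit$beta))
  expect_error(predict(fit, inst$X[, -1, drop = FALSE]), "columns")
  Xbad <- inst$X
  colnames(Xbad) <- rev(colnames(inst$X))
  expect_error(predict(fit, Xbad), "names")
})

test_that("non-finite inputs are rejected", {
  X <- matrix(c(1, NA, 2, 3), 2, 2)
  expect_error(fit_enet(X, c(1, 2), 0.1), "finite")
  expect_error(fit_path(matrix(c(1, Inf, 2, 3), 2), c(1, 2)), "finite")
})
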