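#' Penalty and cross-validation configuration
#'
#' The solver minimizes, for response `y` and design `X` with unpenalized
#' intercept,
#' \deqn{\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^T\beta)^2 +
#'       \lambda\left[\alpha\|\beta\|_1 +
#'       \frac{1-\alpha}{2}\|\beta\|_2^2\right]}
#' so that lambda values are on the conventional `1/(2n)`-loss scale.
#'
#' @param alpha Elastic-net mixing in [0, 1]; 1 is the LASSO, 0 is ridge.
#' @param n_lambda Length of the geometric lambda grid (default 100).
#' @param lambda_min_ratio Smallest grid lambda as a fraction of
#'   `lambda_max`; default `NULL` resolves to 1e-4 when n > p, else 1e-2.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change per sweep (default 1e-7).
#' @param max_sweeps Sweep cap per lambda (default 1e5).
#' @param K Cross-validation folds (default 10).
#' @return A `penalty_config` list.
#' @export
penalty_config <- function(alpha = 1, n_lambda = 100, lambda_min_ratio = NULL,
                           tol = 1e-7, max_sweeps = 1e5, K = 10) {
  stopifnot(alpha >= 0, alpha <= 1, n_lambda >= 1, tol > 0, K >= 2)
  if (!is.null(lambda_min_ratio))
    stopifnot(lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(alpha = alpha, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio, tol = tol,
                 max_sweeps = as.integer(max_sweeps), K = as.integer(K)),
            class = "penalty_config")
}

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)`, the proximal operator of the L1 penalty
#' and the kernel of every coordinate-descent update.
#'
#' @param z Real input (vectorized).
#' @param gamma Nonnegative threshold.
#' @return Shrunken value(s).
#' @export
soft_threshold <- function(z, gamma) {
  if (any(gamma < 0)) stop("gamma must be >= 0", call. = FALSE)
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Smallest penalty with an all-zero solution
#'
#' `max_j |<x_j - mean(x_j), y - mean(y)>| / (n * alpha)`: fitting at any
#' lambda at or above this value gives exactly zero coefficients.
#'
#' @param X Numeric design matrix.
#' @param y Response vector.
#' @param alpha Elastic-net mixing, must be > 0 (ridge never zeroes out).
#' @return The grid anchor lambda.
#' @export
lambda_max <- function(X, y, alpha = 1) {
  if (alpha <= 0) stop("lambda_max is undefined for alpha = 0 (ridge)", call. = FALSE)
  X <- as.matrix(X)
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  max(abs(crossprod(Xc, yc))) / (n * alpha)
}

#' Fit the elastic net at one penalty value
#'
#' Cyclic coordinate descent with soft-threshold updates on the Gram
#' ("covariance") form of the problem; the intercept is unpenalized and
#' recovered in closed form from the column means.  Columns are used as
#' given (no internal re-standardisation); a zero-variance column keeps a
#' zero coefficient.
#'
#' @param X Complete finite numeric matrix (n >= 2).
#' @param y Response vector.
#' @param lambda Penalty weight >= 0.
#' @param cfg A [penalty_config()].
#' @param warm_start Optional initial coefficient vector.
#' @return An `enet_fit`: `intercept`, named `beta`, `lambda`, `alpha`,
#'   `n_sweeps`, `converged`.
#' @export
fit_enet <- function(X, y, lambda, cfg = penalty_config(), warm_start = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("X and y must be finite", call. = FALSE)
  n <- nrow(X)
  stopifnot(n >= 2, length(y) == n, lambda >= 0)
  res <- .cd_path(X, y, lambdas = lambda, alpha = cfg$alpha, tol = cfg$tol,
                  max_sweeps = cfg$max_sweeps, warm_start = warm_start)
  fit <- .make_fit(res, 1L, colnames(X), cfg$alpha)
  if (!fit$converged)
    warning("coordinate descent did not converge within ", cfg$max_sweeps,
            " sweeps at lambda = ", signif(lambda, 4), call. = FALSE)
  fit
}

# Shared centered Gram solve over a lambda vector; returns per-lambda
# coefficients plus the centering info needed for intercepts.
.cd_path <- function(X, y, lambdas, alpha, tol, max_sweeps, warm_start = NULL) {
  n <- nrow(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  G <- crossprod(Xc) / n
  cvec <- as.numeric(crossprod(Xc, y - ym)) / n
  p <- ncol(X)
  init <- if (is.null(warm_start)) numeric(p) else as.numeric(warm_start)
  stopifnot(length(init) == p)
  out <- cd_enet_gram(G, cvec, as.numeric(lambdas), alpha, tol,
                      as.integer(max_sweeps), init)
  out$xm <- xm
  out$ym <- ym
  out$lambdas <- as.numeric(lambdas)
  out
}

.make_fit <- function(res, l, cnames, alpha) {
  beta <- res$beta[, l]
  names(beta) <- cnames
  structure(list(intercept = res$ym - sum(res$xm * beta),
                 beta = beta,
                 lambda = res$lambdas[l], alpha = alpha,
                 n_sweeps = res$sweeps[l],
                 converged = res$converged[l]),
            class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  cat("enet_fit: lambda =", signif(x$lambda, 4), " alpha =", x$alpha,
      " nonzero =", sum(x$beta != 0), "/", length(x$beta),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  invisible(x)
}

#' Fit the whole regularisation path
#'
#' Geometric lambda grid from `lambda_max` down to
#' `lambda_min_ratio * lambda_max`, each solution warm-started from the
#' previous.  For `alpha = 0` the grid is anchored at the `alpha = 0.001`
#' threshold (ridge has no finite all-zero penalty).
#'
#' @inheritParams fit_enet
#' @param lambdas Optional explicit (decreasing) grid overriding the
#'   computed one, e.g. to reuse a full-data grid on a fold.
#' @return An `enet_path`: `lambdas`, coefficient matrix `beta`
#'   (p x n_lambda), `intercepts`, `alpha`, `sweeps`, `converged`.
#' @export
fit_path <- function(X, y, cfg = penalty_config(), lambdas = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("X and y must be finite", call. = FALSE)
  n <- nrow(X)
  if (is.null(lambdas)) {
    lmax <- lambda_max(X, y, alpha = max(cfg$alpha, 1e-3))
    if (lmax <= 0) lmax <- 1e-3  # constant response: grid value is immaterial
    lmr <- cfg$lambda_min_ratio
    if (is.null(lmr)) lmr <- if (n > ncol(X)) 1e-4 else 1e-2
    lambdas <- if (cfg$n_lambda == 1L) lmax else
      exp(seq(log(lmax), log(lmax * lmr), length.out = cfg$n_lambda))
  }
  res <- .cd_path(X, y, lambdas, cfg$alpha, cfg$tol, cfg$max_sweeps)
  beta <- res$beta
  rownames(beta) <- colnames(X)
  structure(list(lambdas = res$lambdas, beta = beta,
                 intercepts = res$ym - as.numeric(crossprod(res$xm, beta)),
                 alpha = cfg$alpha, sweeps = res$sweeps,
                 converged = res$converged),
            class = "enet_path")
}

#' Select lambda by K-fold cross-validation
#'
#' Rows are partitioned into K folds uniformly at random (deterministic by
#' seed).  The lambda grid is computed once on the full data supplied; each
#' training fold is path-fitted on that common grid and scored on its held
#' fold.  `cv_mse` is the mean over folds of the held-fold mean squared
#' error, `cv_se` its standard error over folds; `lambda_min` is the grid
#' argmin with ties broken toward the larger (sparser) lambda.
#'
#' @inheritParams fit_enet
#' @param seed Integer seed for the fold assignment.
#' @return A `cv_curve`: `lambdas`, `cv_mse`, `cv_se`, `lambda_min`,
#'   `index_min`, `fold_assignment`, and `fit` (the full-data `enet_path` on
#'   the same grid).
#' @export
cv_select <- function(X, y, cfg = penalty_config(), seed) {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- cfg$K
  if (K > n) stop("K = ", K, " folds exceed n = ", n, " rows", call. = FALSE)
  full <- fit_path(X, y, cfg)
  lambdas <- full$lambdas
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(K), n))
  mse <- matrix(NA_real_, K, length(lambdas))
  for (k in seq_len(K)) {
    hold <- fold == k
    pk <- fit_path(X[!hold, , drop = FALSE], y[!hold], cfg, lambdas = lambdas)
    pred <- sweep(X[hold, , drop = FALSE] %*% pk$beta, 2L, pk$intercepts, "+")
    mse[k, ] <- colMeans((y[hold] - pred)^2)
  }
  cv_mse <- colMeans(mse)
  cv_se <- apply(mse, 2L, sd) / sqrt(K)
  imin <- which.min(cv_mse)  # grid is decreasing: first minimum = largest lambda
  structure(list(lambdas = lambdas, cv_mse = cv_mse, cv_se = cv_se,
                 lambda_min = lambdas[imin], index_min = imin,
                 fold_assignment = fold, fit = full),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat("cv_curve:", length(x$lambdas), "lambdas | lambda_min =",
      signif(x$lambda_min, 4), " cv_mse =", signif(min(x$cv_mse), 4), "\n")
  invisible(x)
}

#' Predict from a fitted penalized model
#'
#' @param object An `enet_fit`.
#' @param newdata Numeric matrix encoded with the same columns (same
#'   `column_map`/scaling) as the training design.
#' @param ... Unused.
#' @return Predicted log-scale outcomes `intercept + newdata %*% beta`.
#' @export
predict.enet_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta))
    stop("newdata has ", ncol(newdata), " columns; fit expects ",
         length(object$beta), call. = FALSE)
  if (!is.null(colnames(newdata)) && !is.null(names(object$beta)) &&
      !identical(colnames(newdata), names(object$beta)))
    stop("newdata column names do not match the fitted coefficients", call. = FALSE)
  as.numeric(object$intercept + newdata %*% object$beta)
}

#' Karush-Kuhn-Tucker optimality certificate
#'
#' Checks the subgradient conditions of the elastic-net objective at a fit:
#' for zero coordinates `|x_j' r / n| <= lambda * alpha + tol`, and for
#' nonzero coordinates
#' `|x_j' r / n - lambda*(1-alpha)*beta_j - lambda*alpha*sign(beta_j)| <= tol`.
#'
#' @param fit An `enet_fit`.
#' @param X,y The data the fit was computed on.
#' @param tol Certificate tolerance (default 1e-6).
#' @return List with `ok` (logical) and `max_violation`.
#' @export
kkt_check <- function(fit, X, y, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  r <- y - fit$intercept - as.numeric(X %*% fit$beta)
  g <- as.numeric(crossprod(X, r)) / n
  la <- fit$lambda * fit$alpha
  lr <- fit$lambda * (1 - fit$alpha)
  nz <- fit$beta != 0
  viol <- numeric(length(fit$beta))
  viol[!nz] <- pmax(abs(g[!nz]) - la, 0)
  viol[nz] <- abs(g[nz] - lr * fit$beta[nz] - la * sign(fit$beta[nz]))
  list(ok = max(viol) <= tol, max_violation = max(viol))
}

#' Penalized objective value
#'
#' @inheritParams kkt_check
#' @return `(1/2n)*RSS + lambda*(alpha*||beta||_1 + (1-alpha)/2*||beta||_2^2)`.
#' @export
enet_objective <- function(fit, X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  r <- y - fit$intercept - as.numeric(X %*% fit$beta)
  sum(r^2) / (2 * n) +
    fit$lambda * (fit$alpha * sum(abs(fit$beta)) +
                    (1 - fit$alpha) / 2 * sum(fit$beta^2))
}
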