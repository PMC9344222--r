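# Independent oracles for the penalized-regression engine.

# Objective value for arbitrary (b0, beta), matching fit_enet's loss scaling.
obj_value <- function(X, y, b0, beta, lambda, alpha) {
  n <- nrow(X)
  r <- y - b0 - as.numeric(X %*% beta)
  sum(r^2) / (2 * n) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

# Generic convex solver: FISTA (accelerated proximal gradient) on the centered
# problem.  Independent of the coordinate-descent implementation under test.
fista_enet <- function(X, y, lambda, alpha, iters = 20000, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  G <- crossprod(Xc) / n
  cvec <- as.numeric(crossprod(Xc, yc)) / n
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values) +
    lambda * (1 - alpha) + 1e-12
  b <- numeric(p); z <- b; t <- 1
  for (i in seq_len(iters)) {
    grad <- as.numeric(G %*% z) - cvec + lambda * (1 - alpha) * z
    bn <- z - grad / L
    bn <- sign(bn) * pmax(abs(bn) - lambda * alpha / L, 0)
    tn <- (1 + sqrt(1 + 4 * t^2)) / 2
    zn <- bn + (t - 1) / tn * (bn - b)
    if (max(abs(bn - b)) < tol && i > 10) { b <- bn; break }
    b <- bn; z <- zn; t <- tn
  }
  list(beta = b, intercept = ym - sum(xm * b))
}

# Closed-form ridge on centered data: (X'X + n*lambda*I)^-1 X'y.
ridge_closed_form <- function(X, y, lambda) {
  n <- nrow(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  b <- solve(crossprod(Xc) + n * lambda * diag(ncol(X)), crossprod(Xc, yc))
  list(beta = as.numeric(b), intercept = ym - sum(xm * b))
}

# Random small regression instance.
random_instance <- function(seed, n_max = 40, p_max = 6) {
  set.seed(seed)
  n <- sample(8:n_max, 1)
  p <- sample(2:p_max, 1)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p) * rbinom(p, 1, 0.6)
  y <- 1 + as.numeric(X %*% beta) + rnorm(n, sd = 0.5)
  list(X = X, y = y, n = n, p = p)
}

# Small dense-signal design for quick stability runs.
make_signal_design <- function(n = 150, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  y <- 1 + X[, 1] - 0.8 * X[, 2] + rnorm(n, sd = 0.4)
  list(X = X, y = y)
}

# Two-predictor numeric cohort spec with a given latent correlation.
two_numeric_spec <- function(n, r, effects = c(0, 0), noise = 0.35) {
  cohort_spec(
    n = n,
    predictors = list(
      predictor_spec("x1", "numeric", true_effect = effects[1]),
      predictor_spec("x2", "numeric", true_effect = effects[2])
    ),
    latent_correlation = matrix(c(1, r, r, 1), 2),
    noise_sd_log = noise
  )
}
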