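test_that("standardize centres and scales columns with divisor n-1", {
  st <- standardize(matrix(c(2, 4, 6), 3, 1), c(1, 2, 4))
  expect_equal(as.numeric(st$Xs), c(-1, 0, 1))
  # idempotence on already-standardised input
  X <- oracle_scale(matrix(rnorm(40), 10, 4))
  y <- as.numeric(scale(rnorm(10)))
  st2 <- standardize(X, y)
  expect_equal(unname(st2$Xs), unname(X), tolerance = 1e-12)
  expect_error(standardize(matrix(rnorm(10), 5, 2), rep(3, 5)),
               "zero-variance response")
})

test_that("constant predictor columns are dropped into the mask", {
  X <- cbind(rnorm(10), rep(7, 10), rnorm(10))
  st <- standardize(X, rnorm(10))
  expect_equal(st$keep, c(1L, 3L))
  expect_equal(ncol(st$Xs), 2L)
})

test_that("NIPALS matches an independently transcribed textbook oracle", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(6:12, 1); m <- sample(3:6, 1)
    A <- sample(1:min(3, m), 1)
    X <- matrix(rnorm(n * m), n, m)
    y <- rnorm(n)
    st <- standardize(X, y)
    got <- nipals_fit(st$Xs, st$Ys, A)$B
    want <- oracle_nipals_b(st$Xs, st$Ys, A)
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
  }
})

test_that("full-rank PLS equals ordinary least squares", {
  set.seed(7)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- as.numeric(X %*% c(1, -2, 0.5, 3) + rnorm(30))
  fit <- pls_train(X, y, A = 4)
  ols <- unname(lm.fit(cbind(1, X), y)$fitted.values)
  expect_equal(predict(fit, X), ols, tolerance = 1e-6)
})

test_that("univariate proportional response recovers the slope", {
  x <- matrix(rnorm(20), 20, 1)
  y <- 3 * x[, 1]
  fit <- pls_train(x, y, A = 1)
  # back-transformed coefficient: dy/dx = 3
  b <- fit$B[1, 1] * fit$y_scale / fit$x_scale
  expect_equal(unname(b), 3, tolerance = 1e-10)
})

test_that("prediction at the training mean returns the training response mean", {
  set.seed(8)
  X <- matrix(rnorm(60), 15, 4)
  y <- rnorm(15, 10)
  fit <- pls_train(X, y, A = 2)
  yc <- predict(fit, matrix(colMeans(X), 1, 4))
  expect_equal(yc, unname(fit$y_center), tolerance = 1e-10)
  # fitted model beats the mean-only model on the training data
  expect_lte(rmse(y, predict(fit, X)), rmse(y, rep(mean(y), 15)))
})

test_that("perturbations orthogonal to every weight vector leave predictions unchanged", {
  set.seed(9)
  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- rnorm(12)
  fit <- pls_train(X, y, A = 2)
  # construct delta in the orthogonal complement of span(W), on the
  # standardised scale, then map back to the raw scale
  base <- qr.Q(qr(fit$W), complete = TRUE)[, (fit$A + 1):6, drop = FALSE]
  delta_s <- base %*% rnorm(ncol(base))
  x0 <- X[3, ]
  x1 <- x0 + as.numeric(delta_s) * fit$x_scale
  expect_equal(predict(fit, matrix(x1, 1)), predict(fit, matrix(x0, 1)),
               tolerance = 1e-8)
})

test_that("rmse and r2 match their definitions", {
  y <- c(0, 1, 2); yh <- c(0, 1, 3)
  expect_equal(rmse(y, yh), sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(rmse(y, y), 0)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, rep(mean(y), 3)), 0)
  expect_error(rmse(1:3, 1:4), "length")
  expect_error(r2(rep(2, 3), 1:3), "zero-variance")
})

test_that("score vectors are mutually orthogonal and deflation exhausts X", {
  set.seed(10)
  X <- matrix(rnorm(10 * 5), 10, 5)
  y <- rnorm(10)
  st <- standardize(X, y)
  fit <- nipals_fit(st$Xs, st$Ys, 5)
  G <- crossprod(fit$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  # after rank(X) components the residual X is numerically zero
  resid <- st$Xs
  for (a in seq_len(fit$A))
    resid <- resid - tcrossprod(fit$T[, a], fit$P[, a])
  expect_lt(norm(resid, "F"), 1e-8)
})

test_that("single-response NIPALS converges in one inner pass per component", {
  set.seed(11)
  X <- matrix(rnorm(8 * 4), 8, 4)
  y <- rnorm(8)
  st <- standardize(X, y)
  # one-pass variant computed by hand for the first component
  u <- st$Ys[, 1]
  w <- crossprod(st$Xs, u) / sum(u^2); w <- w / sqrt(sum(w^2))
  t1 <- as.numeric(st$Xs %*% w)
  fit <- nipals_fit(st$Xs, st$Ys, 1)
  expect_equal(abs(sum(fit$T[, 1] * t1)) / (sqrt(sum(fit$T[, 1]^2)) * sqrt(sum(t1^2))),
               1, tolerance = 1e-10)
})

test_that("noiseless linear data is recovered exactly at full rank", {
  set.seed(12)
  X <- matrix(rnorm(40 * 5), 40, 5)
  b <- c(2, -1, 0, 0.5, 1)
  y <- as.numeric(X %*% b)
  fit <- pls_train(X, y, A = 5)
  bhat <- as.numeric(fit$B) * fit$y_scale / fit$x_scale
  expect_equal(bhat, b, tolerance = 1e-6)
})

test_that("leave-one-out cross-validation is deterministic", {
  set.seed(13)
  X <- matrix(rnorm(6 * 3), 6, 3)
  y <- rnorm(6)
  c1 <- cross_validate(X, y, A_max = 2, folds = 6, scheme = "random", seed = 1)
  c2 <- cross_validate(X, y, A_max = 2, folds = 6, scheme = "random", seed = 99)
  expect_equal(c1$rmsecv, c2$rmsecv, tolerance = 1e-12)
})

test_that("RMSECV rises with extra components when y is pure noise", {
  set.seed(14)
  worse <- 0
  n_sims <- 30
  for (i in seq_len(n_sims)) {
    X <- matrix(rnorm(30 * 10), 30, 10)
    y <- rnorm(30)
    cv <- cross_validate(X, y, A_max = 6, folds = 5, scheme = "random",
                         seed = i)
    worse <- worse + (cv$rmsecv[6] >= cv$rmsecv[1])
  }
  # overfitting detection: more components should not help, on average
  expect_gt(worse / n_sims, 0.7)
})

test_that("the component selector finds planted latent dimensionality", {
  hits <- 0
  n_sims <- 50
  for (i in seq_len(n_sims)) {
    set.seed(2000 + i)
    n <- 60; m <- 20
    # four latent directions with a variance ladder in X but equal
    # contributions to y: all four must be extracted before y is explained
    Tm <- matrix(rnorm(n * 4), n, 4) %*% diag(c(16, 8, 4, 2))
    L <- matrix(rnorm(4 * m), 4, m)
    X <- Tm %*% L + matrix(rnorm(n * m, sd = 0.05), n, m)
    y <- as.numeric(Tm %*% (1 / c(16, 8, 4, 2)) + rnorm(n, sd = 0.05))
    cv <- cross_validate(X, y, A_max = 8, folds = 5, scheme = "random",
                         seed = i)
    hits <- hits + (select_components(cv) == 4L)
  }
  expect_gte(hits / n_sims, 0.8)
})

test_that("the parsimony rule picks the smallest near-optimal component count", {
  expect_equal(select_components(c(5, 2, 1.0, 0.99, 0.99), rel_tol = 0.05), 3L)
  expect_equal(select_components(c(1, 1, 1)), 1L)
  expect_equal(select_components(2.5), 1L)
})

test_that("model JSON serialisation round trips predictions", {
  set.seed(15)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- rnorm(20)
  fit <- pls_train(X, y, A = 3, mask = c(1L, 2L, 4L, 5L, 6L))
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_model(fit, path)
  fit2 <- read_pls_model(path)
  expect_equal(predict(fit2, X), predict(fit, X), tolerance = 1e-12)
  expect_equal(fit2$variable_mask, fit$variable_mask)
})
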