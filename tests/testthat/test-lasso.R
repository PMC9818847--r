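test_that("unregularized lasso reproduces OLS on a full-rank design", {
  set.seed(1)
  Z <- matrix(rnorm(120), 30, 4)
  y <- as.vector(Z %*% c(2, -1, 0.5, 0)) + rnorm(30, sd = 0.2)
  fit <- lasso_fit(Z, y, lambda = 0)
  b <- ols_coefs(Z, y)
  expect_equal(fit$beta0, b[1], tolerance = 1e-6)
  expect_equal(fit$beta, b[-1], tolerance = 1e-6)
})

test_that("a penalty at or above lambda_max shrinks everything to zero", {
  set.seed(2)
  Z <- matrix(rnorm(150), 30, 5)
  y <- as.vector(Z %*% rnorm(5)) + rnorm(30)
  st <- iplslasso:::lasso_standardize(Z)
  lambda_max <- max(abs(crossprod(st$Zs, y - mean(y))) / nrow(Z))
  fit <- lasso_fit(Z, y, lambda = lambda_max * 1.0001)
  expect_equal(fit$beta, rep(0, 5))
  expect_equal(fit$beta0, mean(y))
  expect_length(fit$selected, 0)
})

test_that("orthonormal designs give the closed-form soft-threshold solution", {
  set.seed(3)
  n <- 40
  G <- scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)
  Q <- qr.Q(qr(G))
  Z <- sqrt(n) * Q                       # mean 0, population sd 1, orthogonal
  y <- as.vector(Z %*% c(1.5, -0.4, 0.05)) + rnorm(n, sd = 0.1)
  yc <- y - mean(y)
  ols_std <- as.vector(crossprod(Z, yc)) / n
  for (lambda in c(0.02, 0.2, 0.6)) {
    fit <- lasso_fit(Z, y, lambda)
    want <- sign(ols_std) * pmax(abs(ols_std) - lambda, 0)
    expect_equal(fit$beta, want, tolerance = 1e-6)
  }
})

test_that("KKT conditions hold at returned solutions", {
  for (seed in 1:6) {
    set.seed(seed)
    Z <- matrix(rnorm(35 * 5), 35, 5)
    y <- as.vector(Z %*% rnorm(5)) + rnorm(35)
    lambda <- runif(1, 0.05, 0.5)
    fit <- lasso_fit(Z, y, lambda)
    st <- iplslasso:::lasso_standardize(Z)
    beta_std <- fit$beta * st$sd
    r <- (y - mean(y)) - as.vector(st$Zs %*% beta_std)
    g <- -as.vector(crossprod(st$Zs, r)) / nrow(Z)
    for (j in 1:5) {
      if (beta_std[j] != 0) {
        expect_lt(abs(g[j] + lambda * sign(beta_std[j])), 1e-5)
      } else {
        expect_lte(abs(g[j]), lambda + 1e-5)
      }
    }
  }
})

test_that("the solution path runs from empty to the OLS support", {
  set.seed(4)
  Z <- matrix(rnorm(40 * 4), 40, 4)
  y <- as.vector(Z %*% c(2, -1, 1, 0.5)) + rnorm(40, sd = 0.1)
  st <- iplslasso:::lasso_standardize(Z)
  lambda_max <- max(abs(crossprod(st$Zs, y - mean(y))) / nrow(Z))
  expect_length(lasso_fit(Z, y, lambda_max)$selected, 0)
  expect_length(lasso_fit(Z, y, lambda_max * 1e-5)$selected, 4)
})

test_that("lasso agrees with glmnet along the path", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  Z <- matrix(rnorm(60 * 6), 60, 6)
  y <- as.vector(Z %*% c(3, 0, -2, 0, 1, 0)) + rnorm(60, sd = 0.5)
  for (lambda in c(0.05, 0.3, 0.8)) {
    mine <- lasso_fit(Z, y, lambda)
    ref <- glmnet::glmnet(Z, y, lambda = lambda, thresh = 1e-12,
                          standardize = TRUE)
    expect_equal(mine$beta, as.vector(coef(ref))[-1], tolerance = 1e-6)
    expect_equal(mine$beta0, as.vector(coef(ref))[1], tolerance = 1e-6)
  }
})

test_that("cross-validated lambda keeps a noiseless informative column", {
  set.seed(6)
  Z <- matrix(rnorm(50 * 4), 50, 4)
  y <- 2 * Z[, 3]
  folds <- make_folds(50, 5, seed = 1)
  sel <- select_lambda(Z, y, folds)
  fit <- lasso_fit(Z, y, sel$lambda)
  expect_true(3 %in% fit$selected)
})

test_that("pure-noise problems select at most one member in most seeds", {
  sparse <- 0
  for (seed in 1:20) {
    res <- iplslasso:::with_local_seed(100 + seed, {
      Z <- matrix(rnorm(40 * 6), 40, 6)
      y <- rnorm(40)
      folds <- make_folds(40, 5, seed = seed)
      sel <- select_lambda(Z, y, folds)
      length(lasso_fit(Z, y, sel$lambda)$selected)
    })
    sparse <- sparse + (res <= 1)
  }
  expect_gte(sparse, 16)   # >= 80% of seeds
})

test_that("duplicated columns leave the CV curve unchanged after merging", {
  set.seed(7)
  z1 <- rnorm(30); z3 <- rnorm(30)
  y <- 1.5 * z1 + rnorm(30, sd = 0.3)
  Z_dup <- cbind(z1, z1, z3)
  Z_merged <- cbind(z1, z3)
  folds <- make_folds(30, 5, seed = 2)
  cv_dup <- select_lambda(Z_dup, y, folds)
  cv_merged <- select_lambda(Z_merged, y, folds)
  # same lambda grid (lambda_max depends only on max correlation) and the
  # same cross-validated error curve
  expect_equal(cv_dup$cv$lambda, cv_merged$cv$lambda, tolerance = 1e-10)
  expect_equal(cv_dup$cv$mean_mse, cv_merged$cv$mean_mse, tolerance = 1e-6)
})

test_that("constant columns are dropped harmlessly", {
  set.seed(8)
  Z <- cbind(rnorm(25), 5, rnorm(25))
  y <- 2 * Z[, 1] + rnorm(25, sd = 0.1)
  fit <- lasso_fit(Z, y, lambda = 0.01)
  expect_equal(fit$beta[2], 0)
  expect_true(1 %in% fit$selected)
})
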