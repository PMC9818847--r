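# Lasso by cyclic coordinate descent. The solver is the selection-and-fusion
# engine applied to the member-model output matrix Z (samples x members); it
# is deliberately self-contained so its KKT conditions can be verified
# directly in tests.

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Standardization statistics for the solver: population (1/N) variance, the
# dominant software convention for this objective.
lasso_standardize <- function(Z) {
  m <- colMeans(Z)
  s <- sqrt(colMeans(sweep(Z, 2, m)^2))
  active <- s > 1e-12
  Zs <- sweep(Z, 2, m)
  Zs[, active] <- sweep(Zs[, active, drop = FALSE], 2, s[active], `/`)
  Zs[, !active] <- 0
  list(Zs = Zs, mean = m, sd = s, active = active)
}

# Cyclic coordinate descent in covariance form: G = Z'Z/n (unit diagonal for
# standardized columns), g = Z'y/n, with the running vector s = G beta kept
# incrementally so one coordinate update costs O(p) regardless of n.
# Objective: (1/(2N)) * ||yc - Zs b||^2 + lambda * ||b||_1.
#
# Two stopping rules: the coordinate rule (max |delta beta| < tol) and an
# objective-flatness rule for near-collinear designs, where coefficients can
# wander along an almost-flat valley while predictions have long converged.
# Each exact coordinate update decreases the objective by at least
# (delta beta)^2 / 2 (unit-variance columns), so once a full sweep's summed
# guaranteed decrease falls below 1e-12 * var(y) no meaningful progress is
# possible. Well-conditioned problems hit the coordinate rule first.
# Between full sweeps, inner sweeps cycle over the nonzero coordinates only
# (active-set iteration); the final full sweep certifies convergence.
lasso_cd_cov <- function(G, g, lambda, beta = NULL, active = NULL,
                         tol = 1e-7, kkt_tol = 1e-8, flat_tol = 0,
                         max_sweeps = 1e5) {
  p <- length(g)
  if (is.null(beta)) beta <- numeric(p)
  if (is.null(active)) active <- rep(TRUE, p)
  res <- .cd_cov_cpp(G, g, kkt_tol, flat_tol, lambda, beta, active, tol,
                     max_sweeps)
  if (!res$converged) {
    abort(sprintf("coordinate descent did not converge in %g sweeps",
                  max_sweeps),
          class = "iplslasso_convergence_error")
  }
  list(beta = res$beta, sweeps = res$sweeps)
}

# Convenience wrapper on raw standardized data (used by lasso_fit and tests).
lasso_cd <- function(Zs, yc, lambda, beta = NULL, active = NULL,
                     tol = 1e-7, max_sweeps = 1e5) {
  n <- nrow(Zs)
  lasso_cd_cov(crossprod(Zs) / n, as.vector(crossprod(Zs, yc)) / n,
               lambda, beta = beta, active = active,
               tol = tol, flat_tol = 1e-9 * mean(yc^2),
               max_sweeps = max_sweeps)
}

#' Fit a Lasso regression
#'
#' Minimizes `(1/(2N)) * sum((y - beta0 - Z beta)^2) + lambda * sum(|beta|)`
#' by cyclic coordinate descent. Columns of `Z` are centered and scaled to
#' unit (population) variance inside the solver; coefficients are mapped back
#' to the original scale and the unpenalized intercept recovered from the
#' means. Back-scaled coefficients with magnitude below `zero_tol` are
#' reported as exact zeros (discarded members). In the unscaled objective
#' `sum((...)^2) + lambda_u * sum(|beta|)` the equivalent penalty is
#' `lambda_u = 2 * N * lambda`.
#'
#' @param Z Numeric matrix (samples x members).
#' @param y Numeric response vector.
#' @param lambda Non-negative regularization weight (on the `1/(2N)` scale).
#' @param zero_tol Magnitude below which a back-scaled coefficient is set to
#'   exactly zero (default 1e-10).
#' @return A list with `beta0` (intercept, HU), `beta` (original-scale
#'   coefficients, exact zeros outside the support), `lambda`, `selected`
#'   (1-based indices of nonzero coefficients) and `sweeps`.
#' @examples
#' Z <- matrix(rnorm(60), 20)
#' y <- 2 * Z[, 1] + rnorm(20, sd = 0.1)
#' lasso_fit(Z, y, lambda = 0.05)$selected
#' @export
lasso_fit <- function(Z, y, lambda, zero_tol = 1e-10) {
  Z <- check_numeric_matrix(Z, "Z")
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(Z), lambda >= 0)
  st <- lasso_standardize(Z)
  yc <- y - mean(y)
  fit <- lasso_cd(st$Zs, yc, lambda, active = st$active)
  beta <- numeric(ncol(Z))
  beta[st$active] <- fit$beta[st$active] / st$sd[st$active]
  beta[abs(beta) < zero_tol] <- 0
  beta0 <- mean(y) - sum(beta * st$mean)
  list(beta0 = beta0, beta = beta, lambda = lambda,
       selected = which(beta != 0), sweeps = fit$sweeps)
}

# Solutions along a decreasing lambda grid with warm starts, on standardized
# data (internal; used by cross-validated lambda selection). The Gram matrix
# is formed once for the whole path.
lasso_path_std <- function(Zs, yc, lambdas, active) {
  n <- nrow(Zs)
  G <- crossprod(Zs) / n
  g <- as.vector(crossprod(Zs, yc)) / n
  flat_tol <- 1e-9 * mean(yc^2)
  betas <- matrix(0, ncol(Zs), length(lambdas))
  beta <- numeric(ncol(Zs))
  for (i in seq_along(lambdas)) {
    beta <- lasso_cd_cov(G, g, lambdas[i], beta = beta, active = active,
                         flat_tol = flat_tol)$beta
    betas[, i] <- beta
  }
  betas
}

#' Select the Lasso penalty by cross-validation
#'
#' Builds a grid of 100 log-spaced penalties from `lambda_max` (the smallest
#' penalty shrinking every coefficient to zero) down to `lambda_max * 1e-4`,
#' computes the 5-fold cross-validated mean squared error at each grid point
#' (standardization statistics refit within each training fold, warm starts
#' along the path) and returns the penalty at the minimum mean MSE; ties go
#' to the larger penalty (the sparser model).
#'
#' @param Z Numeric matrix (samples x members); a single column is allowed.
#' @param y Numeric response vector.
#' @param folds A `fold_scheme` (conventionally 5-fold).
#' @param n_lambda Grid size (default 100).
#' @return A list with `lambda` (selected penalty), `lambda_max` and `cv`
#'   (tibble with columns `lambda`, `mean_mse`).
#' @export
select_lambda <- function(Z, y, folds, n_lambda = 100) {
  Z <- check_numeric_matrix(Z, "Z")
  y <- as.numeric(y)
  n <- nrow(Z)
  check_folds(folds, n)
  st <- lasso_standardize(Z)
  if (!any(st$active)) {
    return(list(lambda = 0, lambda_max = 0,
                cv = tibble(lambda = numeric(0), mean_mse = numeric(0))))
  }
  yc <- y - mean(y)
  lambda_max <- max(abs(crossprod(st$Zs, yc)) / n)
  if (lambda_max < 1e-12) {
    return(list(lambda = 0, lambda_max = lambda_max,
                cv = tibble(lambda = numeric(0), mean_mse = numeric(0))))
  }
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * 1e-4),
                     length.out = n_lambda))
  se <- matrix(NA_real_, n, n_lambda)    # squared out-of-fold errors
  for (held in folds) {
    train <- setdiff(seq_len(n), held)
    st_tr <- lasso_standardize(Z[train, , drop = FALSE])
    y_tr <- y[train]
    betas <- lasso_path_std(st_tr$Zs, y_tr - mean(y_tr), lambdas, st_tr$active)
    # back-transform and predict the held-out rows at every lambda
    b_orig <- betas
    b_orig[st_tr$active, ] <- betas[st_tr$active, , drop = FALSE] /
      st_tr$sd[st_tr$active]
    b_orig[!st_tr$active, ] <- 0
    b0 <- mean(y_tr) - as.vector(crossprod(b_orig, st_tr$mean))
    pred <- Z[held, , drop = FALSE] %*% b_orig +
      matrix(b0, length(held), n_lambda, byrow = TRUE)
    se[held, ] <- (pred - y[held])^2
  }
  mean_mse <- colMeans(se)
  best <- which.min(mean_mse)            # first = largest lambda on ties
  list(lambda = lambdas[best], lambda_max = lambda_max,
       cv = tibble(lambda = lambdas, mean_mse = mean_mse))
}
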