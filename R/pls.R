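#' Fit a PLS1 regression model (NIPALS)
#'
#' Mean-centered NIPALS partial least squares with a single response.
#' Neither `X` nor `y` is variance-scaled. The regression vector `B` maps raw
#' spectra to predictions via `(x - x_mean) %*% B + y_mean` and reproduces
#' the deflation recursion exactly.
#'
#' @param X Numeric matrix (samples x variables).
#' @param y Numeric response vector (HU).
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(20, ncol(X),
#'   nrow(X) - 1)` (capped automatically if deflation exhausts X early).
#' @param column_index Optional integer vector recording which columns of a
#'   larger dataset this model consumes (used by interval models).
#' @return An object of class `pls_model` with elements `x_mean`, `y_mean`,
#'   `W`, `P`, `q`, `B`, `n_lv`, `column_index`.
#' @examples
#' X <- matrix(rnorm(200), 20)
#' y <- X[, 1] - 2 * X[, 5] + rnorm(20, sd = 0.1)
#' m <- fit_pls(X, y, n_lv = 3)
#' head(predict(m, X))
#' @export
fit_pls <- function(X, y, n_lv, column_index = NULL) {
  X <- check_numeric_matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(is.finite(y)))
  if (sd(y) == 0) {
    abort("response has zero variance", class = "iplslasso_fit_error")
  }
  lv_cap <- min(20L, ncol(X), nrow(X) - 1L)
  if (n_lv < 1 || n_lv > lv_cap) {
    abort(sprintf("n_lv must be in [1, %d]", lv_cap),
          class = "iplslasso_bounds_error")
  }
  core <- pls_nipals(X, y, n_lv)
  structure(
    c(core, list(column_index = column_index %||% seq_len(ncol(X)))),
    class = "pls_model"
  )
}

# NIPALS PLS1 core. Returns centering statistics, weights W, loadings P,
# y-loadings q, and regression vectors for every component count 1..n_lv
# (B_all, used by cross-validation); B is the n_lv-component vector.
pls_nipals <- function(X, y, n_lv) {
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  q <- numeric(n_lv)
  k_used <- 0L
  for (k in seq_len(n_lv)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break        # X deflated to numerical noise
    w <- w / nw
    t_k <- Xc %*% w
    tt <- sum(t_k^2)
    if (tt < 1e-24) break
    p_k <- crossprod(Xc, t_k) / tt
    q_k <- sum(yc * t_k) / tt
    Xc <- Xc - t_k %*% t(p_k)
    yc <- yc - t_k * q_k
    W[, k] <- w; P[, k] <- p_k; q[k] <- q_k
    k_used <- k
  }
  B_all <- matrix(0, p, n_lv)
  if (k_used == 0L) {
    # X carries no covariance with y at all; the model predicts the mean
    W <- W[, 1, drop = FALSE]; P <- P[, 1, drop = FALSE]; q <- 0
  } else {
    W <- W[, seq_len(k_used), drop = FALSE]
    P <- P[, seq_len(k_used), drop = FALSE]
    q <- q[seq_len(k_used)]
    R <- crossprod(P, W)         # upper triangular, unit diagonal
    for (k in seq_len(k_used)) {
      alpha <- backsolve(R[seq_len(k), seq_len(k), drop = FALSE],
                         q[seq_len(k)])
      B_all[, k] <- W[, seq_len(k), drop = FALSE] %*% alpha
    }
    if (k_used < n_lv) {
      for (k in seq((k_used + 1L), n_lv)) B_all[, k] <- B_all[, k_used]
    }
  }
  list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, q = q,
       B = B_all[, n_lv], B_all = B_all, n_lv = n_lv,
       n_lv_effective = max(k_used, 1L))
}

#' Predict from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Numeric matrix whose columns match the columns the model
#'   was fitted on, or a full-width matrix / `spectra_set` from which
#'   `object$column_index` is extracted.
#' @param ... Unused.
#' @return Numeric vector of predicted reference values.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$X
  newdata <- check_numeric_matrix(newdata, "newdata")
  p_model <- length(object$x_mean)
  if (ncol(newdata) != p_model) {
    ci <- object$column_index
    if (!is.null(ci) && ncol(newdata) >= max(ci)) {
      newdata <- newdata[, ci, drop = FALSE]
    } else {
      abort(sprintf("newdata has %d columns; model expects %d",
                    ncol(newdata), p_model),
            class = "iplslasso_shape_error")
    }
  }
  as.vector(sweep(newdata, 2, object$x_mean) %*% object$B) + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d variables, %d latent variable(s)\n",
              length(x$B), x$n_lv))
  invisible(x)
}

#' Cross-validate the latent-variable count
#'
#' For each latent-variable count `1..max_lv`, out-of-fold predictions are
#' assembled over all folds (the model is refit inside every training fold)
#' and RMSECV computed; the selected count minimizes RMSECV, with ties broken
#' toward the smallest count (parsimony).
#'
#' @param X Numeric matrix (samples x variables).
#' @param y Numeric response vector.
#' @param max_lv Maximum latent-variable count to try (default 20); capped at
#'   `min(max_lv, ncol(X), smallest training-fold size - 2)`.
#' @param folds A `fold_scheme` from [make_folds()].
#' @return A list of class `pls_cv`: `rmsecv` (numeric per LV), `selected`
#'   (chosen count), `cv_pred` (samples x LV matrix of out-of-fold
#'   predictions) and `max_lv`.
#' @export
cross_validate_lv <- function(X, y, max_lv = 20, folds) {
  X <- check_numeric_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  check_folds(folds, n)
  min_train <- n - max(lengths(folds))
  if (min_train < 2) {
    abort("a fold leaves fewer than 2 training samples",
          class = "iplslasso_fold_error")
  }
  max_lv <- min(max_lv, ncol(X), min_train - 2L, 20L)
  max_lv <- max(1L, max_lv)
  cv_pred <- matrix(NA_real_, n, max_lv)
  for (held in folds) {
    train <- setdiff(seq_len(n), held)
    fit <- pls_nipals(X[train, , drop = FALSE], y[train], max_lv)
    Xc <- sweep(X[held, , drop = FALSE], 2, fit$x_mean)
    cv_pred[held, ] <- Xc %*% fit$B_all + fit$y_mean
  }
  rmsecv <- sqrt(colMeans((cv_pred - y)^2))
  selected <- which.min(rmsecv)   # first minimum = smallest LV on ties
  structure(list(rmsecv = rmsecv, selected = selected,
                 cv_pred = cv_pred, max_lv = max_lv),
            class = "pls_cv")
}

#' Regression performance metrics
#'
#' Root-mean-squared error, Pearson correlation and bias between measured
#' and predicted values, the three statistics used at every calibration and
#' prediction stage.
#'
#' @param y_true Measured reference values.
#' @param y_pred Predicted values, same length (>= 2).
#' @return A one-row tibble with columns `rmse`, `r`, `bias` (all in HU;
#'   `bias = mean(y_pred - y_true)`).
#' @examples
#' regression_metrics(c(1, 2, 3), c(1.1, 2.1, 3.1))
#' @export
regression_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    abort("need two equal-length vectors with at least 2 values",
          class = "iplslasso_input_error")
  }
  if (sd(y_true) == 0 || sd(y_pred) == 0) {
    abort("correlation undefined: zero variance", class = "iplslasso_input_error")
  }
  e <- y_pred - y_true
  tibble(rmse = sqrt(mean(e^2)), r = cor(y_true, y_pred), bias = mean(e))
}

#' @rdname fit_pls
#' @param x,object A `pls_model`.
#' @param ... Unused.
#' @export
tidy.pls_model <- function(x, ...) {
  tibble(term = x$column_index, estimate = x$B)
}

#' @rdname fit_pls
#' @export
glance.pls_model <- function(x, ...) {
  tibble(n_lv = x$n_lv, n_lv_effective = x$n_lv_effective,
         n_variables = length(x$B))
}
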