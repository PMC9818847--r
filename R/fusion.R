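#' Fit an iPLS-Lasso fusion model
#'
#' Fits the interval member models ([fit_ipls()]), takes their
#' cross-validated outputs as the fusion design matrix `Z`, selects the
#' Lasso penalty by 5-fold cross-validation ([select_lambda()]) and fits the
#' final Lasso on all calibration rows. Members whose coefficients are
#' exactly zero are discarded; the survivors define the selected spectral
#' intervals. With a single interval (`n = 1`) there is only one member
#' model, which is itself the fusion model: the fusion is the identity on
#' the full-spectrum PLS member.
#'
#' @param cal A `spectra_set` with reference values.
#' @param n Interval count.
#' @param folds A `fold_scheme` over the calibration samples.
#' @param max_lv Maximum latent-variable count per member (default 20).
#' @param ims Optional pre-fitted `ipls_model_set` for this `cal`/`n`/`folds`
#'   (skips refitting the members).
#' @return An object of class `fusion_model`: list with `n`, `beta0`,
#'   `beta` (length n, exact zeros outside the support), `lambda`,
#'   `selected` (1-based surviving member indices), `label` (e.g. `"10/26"`),
#'   `members` (the `ipls_model_set`) and `cv_fitted` (fusion applied to the
#'   members' cross-validated outputs).
#' @export
fit_ipls_lasso <- function(cal, n, folds, max_lv = 20, ims = NULL) {
  if (is.null(ims)) ims <- fit_ipls(cal, n, folds, max_lv = max_lv)
  stopifnot(inherits(ims, "ipls_model_set"))
  y <- ims$y
  if (n == 1) {
    beta0 <- 0; beta <- 1; lambda <- NA_real_; selected <- 1L
    cv_fitted <- ims$cv_outputs[, 1]
  } else {
    Z <- ims$cv_outputs
    sel <- select_lambda(Z, y, folds)
    lambda <- sel$lambda
    fit <- lasso_fit(Z, y, lambda)
    beta0 <- fit$beta0; beta <- fit$beta; selected <- fit$selected
    cv_fitted <- as.vector(Z %*% beta) + beta0
  }
  structure(
    list(n = n, beta0 = beta0, beta = beta, lambda = lambda,
         selected = selected, label = paste0(length(selected), "/", n),
         members = ims, cv_fitted = cv_fitted),
    class = "fusion_model"
  )
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> iPLS-L%d: %s members selected (lambda %.4g)\n",
              x$n, x$label, x$lambda))
  invisible(x)
}

#' Predict from a fusion model
#'
#' Applies the member models to new spectra and combines their outputs with
#' the fused Lasso coefficients.
#'
#' @param object A `fusion_model`.
#' @param newdata Full-width spectral matrix or `spectra_set`.
#' @param ... Unused.
#' @return Numeric vector of predicted reference values.
#' @export
predict.fusion_model <- function(object, newdata, ...) {
  Zp <- predict_members(object$members, newdata)
  if (object$n == 1) return(Zp[, 1])
  as.vector(Zp %*% object$beta) + object$beta0
}

#' @rdname fit_ipls_lasso
#' @param x,object A `fusion_model`.
#' @param ... Unused.
#' @export
tidy.fusion_model <- function(x, ...) {
  div <- x$members$division
  tibble(
    member = seq_len(x$n),
    label = paste0(seq_len(x$n), "/", x$n),
    start = div$start, end = div$end,
    estimate = x$beta,
    selected = seq_len(x$n) %in% x$selected
  )
}

#' @rdname fit_ipls_lasso
#' @export
glance.fusion_model <- function(x, ...) {
  m <- regression_metrics(x$members$y, x$cv_fitted)
  tibble(n = x$n, n_selected = length(x$selected), label = x$label,
         lambda = x$lambda, rmsecv = m$rmse, r_cv = m$r, bias_cv = m$bias)
}

fusion_stage_metrics <- function(fm, pred) {
  cal_m <- regression_metrics(fm$members$y, fm$cv_fitted)
  pred_m <- regression_metrics(pred$y, predict(fm, pred))
  tibble(
    rmsecv = cal_m$rmse, r_cv = cal_m$r, bias_cv = cal_m$bias,
    rmsep = pred_m$rmse, r_p = pred_m$r, bias_p = pred_m$bias
  )
}

#' Sweep the interval-division count
#'
#' For every division `n = 1..n_max`, fits the iPLS-Lasso fusion model on
#' the calibration set and evaluates it at both stages: RMSECV / r_cv /
#' bias_cv from the fusion applied to the members' cross-validated outputs,
#' and RMSEP / r_p / bias_p from the fusion applied to prediction-stage
#' member outputs on the held-out set. The recommended division `best_n`
#' minimizes RMSEP among divisions whose RMSECV lies within
#' `cv_margin` (default 5%) of the global minimum RMSECV, so that predictive
#' performance is weighed alongside cross-validation performance and
#' overfitted divisions are not picked on RMSECV alone.
#'
#' @param cal,pred Calibration and prediction `spectra_set`s sharing one
#'   wavelength axis.
#' @param n_max Largest division count (default 40).
#' @param folds A `fold_scheme` over the calibration samples.
#' @param max_lv Maximum latent-variable count per member (default 20).
#' @param cv_margin Relative RMSECV tolerance defining the candidate set for
#'   `best_n` (default 0.05).
#' @param keep_models Keep every fitted `fusion_model` in the result
#'   (default `FALSE`; the `best_n` model is always kept).
#' @return An object of class `ipls_sweep`: a tibble with one row per
#'   division (`n`, `rmsecv`, `r_cv`, `bias_cv`, `rmsep`, `r_p`, `bias_p`,
#'   `n_selected`, `label`, `selected_list`) plus attributes `best_n` and
#'   `best_model` (and `models` when `keep_models = TRUE`).
#' @export
sweep_divisions <- function(cal, pred, n_max = 40, folds, max_lv = 20,
                            cv_margin = 0.05, keep_models = FALSE) {
  stopifnot(inherits(cal, "spectra_set"), inherits(pred, "spectra_set"))
  if (!isTRUE(all.equal(cal$wavelengths, pred$wavelengths))) {
    abort("calibration and prediction sets must share the wavelength axis",
          class = "iplslasso_axis_error")
  }
  models <- vector("list", n_max)
  rows <- vector("list", n_max)
  for (n in seq_len(n_max)) {
    fm <- fit_ipls_lasso(cal, n, folds, max_lv = max_lv)
    models[[n]] <- fm
    rows[[n]] <- dplyr::bind_cols(
      tibble(n = n),
      fusion_stage_metrics(fm, pred),
      tibble(n_selected = length(fm$selected), label = fm$label,
             selected_list = paste(fm$selected, collapse = ";"))
    )
  }
  tab <- dplyr::bind_rows(rows)
  candidates <- which(tab$rmsecv <= min(tab$rmsecv) * (1 + cv_margin))
  best_n <- candidates[which.min(tab$rmsep[candidates])]
  structure(
    tab,
    best_n = best_n,
    best_model = models[[best_n]],
    models = if (keep_models) models else NULL,
    cv_margin = cv_margin,
    class = c("ipls_sweep", class(tab))
  )
}

#' @export
print.ipls_sweep <- function(x, ...) {
  cat(sprintf("<ipls_sweep> divisions 1..%d, recommended n = %d\n",
              nrow(x), attr(x, "best_n")))
  NextMethod()
}

#' @rdname sweep_divisions
#' @param x An `ipls_sweep`.
#' @param ... Unused.
#' @export
glance.ipls_sweep <- function(x, ...) {
  best_n <- attr(x, "best_n")
  row <- x[x$n == best_n, ]
  tibble(best_n = best_n, rmsecv = row$rmsecv, rmsep = row$rmsep,
         r_p = row$r_p, n_selected = row$n_selected, label = row$label)
}

pls_stage_metrics <- function(model, cv, y_cal, pred) {
  cal_m <- regression_metrics(y_cal, cv$cv_pred[, cv$selected])
  pred_m <- regression_metrics(pred$y, predict(model, pred$X))
  tibble(
    n_lv = model$n_lv,
    rmsecv = cal_m$rmse, r_cv = cal_m$r, bias_cv = cal_m$bias,
    rmsep = pred_m$rmse, r_p = pred_m$r, bias_p = pred_m$bias
  )
}

#' Full-spectrum PLS baseline
#'
#' Fits the plain PLS model on all wavelengths with its latent-variable
#' count chosen by cross-validation, and evaluates both stages.
#'
#' @param cal,pred Calibration and prediction `spectra_set`s.
#' @param folds A `fold_scheme`.
#' @param max_lv Maximum latent-variable count (default 20).
#' @return A list with `model` (`pls_model`), `cv` (`pls_cv`) and `metrics`
#'   (one-row tibble with `n_lv`, both-stage RMSE / r / bias).
#' @export
fit_pls_baseline <- function(cal, pred, folds, max_lv = 20) {
  cv <- cross_validate_lv(cal$X, cal$y, max_lv = max_lv, folds = folds)
  model <- fit_pls(cal$X, cal$y, n_lv = cv$selected)
  list(model = model, cv = cv,
       metrics = pls_stage_metrics(model, cv, cal$y, pred))
}

#' Stacked comparator: PLS on the selected intervals (PLS-s1)
#'
#' One PLS model on the concatenated columns of the intervals a fusion model
#' selected, with the latent-variable count chosen by cross-validation —
#' the selected-interval combination used directly, without optimizing the
#' combination.
#'
#' @param cal,pred Calibration and prediction `spectra_set`s.
#' @param fusion A fitted `fusion_model` with at least one selected member.
#' @param folds A `fold_scheme`.
#' @param max_lv Maximum latent-variable count (default 20).
#' @return A list with `model`, `columns` and `metrics` (as in
#'   [fit_pls_baseline()]).
#' @export
fit_pls_s1 <- function(cal, pred, fusion, folds, max_lv = 20) {
  stopifnot(inherits(fusion, "fusion_model"))
  if (length(fusion$selected) < 1) {
    abort("fusion model selected no intervals", class = "iplslasso_selection_error")
  }
  div <- fusion$members$division
  cols <- unlist(lapply(fusion$selected, function(j) interval_columns(div, j)))
  Xs <- cal$X[, cols, drop = FALSE]
  cv <- cross_validate_lv(Xs, cal$y, max_lv = max_lv, folds = folds)
  model <- fit_pls(Xs, cal$y, n_lv = cv$selected, column_index = cols)
  pred_m <- regression_metrics(pred$y, predict(model, pred$X))
  cal_m <- regression_metrics(cal$y, cv$cv_pred[, cv$selected])
  list(model = model, columns = cols,
       metrics = tibble(n_lv = model$n_lv,
                        rmsecv = cal_m$rmse, r_cv = cal_m$r, bias_cv = cal_m$bias,
                        rmsep = pred_m$rmse, r_p = pred_m$r, bias_p = pred_m$bias))
}

#' Stacked comparator: unpenalized member stack (PLS-s2)
#'
#' Ordinary least squares of the response on all member cross-validated
#' outputs plus an intercept — the stacked fusion of every member model with
#' no selection. A rank-deficient stack is resolved by the minimum-norm
#' solution with a warning.
#'
#' @param cal,pred Calibration and prediction `spectra_set`s.
#' @param ims A fitted `ipls_model_set`.
#' @return A list with `coef` (intercept first) and `metrics` (both-stage
#'   tibble); prediction-stage member outputs feed the prediction metrics.
#' @export
fit_pls_s2 <- function(cal, pred, ims) {
  stopifnot(inherits(ims, "ipls_model_set"))
  Z <- cbind(1, ims$cv_outputs)
  coefs <- as.vector(pinv_solve(Z, ims$y))
  cal_fit <- as.vector(Z %*% coefs)
  Zp <- cbind(1, predict_members(ims, pred$X))
  pred_fit <- as.vector(Zp %*% coefs)
  cal_m <- regression_metrics(ims$y, cal_fit)
  pred_m <- regression_metrics(pred$y, pred_fit)
  list(coef = coefs,
       metrics = tibble(rmsecv = cal_m$rmse, r_cv = cal_m$r, bias_cv = cal_m$bias,
                        rmsep = pred_m$rmse, r_p = pred_m$r, bias_p = pred_m$bias))
}
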