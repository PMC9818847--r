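#' Divide the wavelength axis into equal-width intervals
#'
#' Partitions `p` variables into `n` contiguous, disjoint intervals whose
#' widths differ by at most one: the base width is `floor(p / n)` and the
#' first `p %% n` intervals receive one extra variable.
#'
#' @param p Total variable count.
#' @param n Interval count, `1 <= n <= p`.
#' @return An object of class `interval_division`: a tibble with columns
#'   `interval` (1-based), `start`, `end` (1-based inclusive column range)
#'   and `width`, plus attributes `p` and `n`.
#' @examples
#' divide_intervals(2041, 6)   # widths 341, 340, 340, 340, 340, 340
#' @export
divide_intervals <- function(p, n) {
  p <- as.integer(p); n <- as.integer(n)
  if (n < 1 || n > p) {
    abort(sprintf("interval count %d must lie in [1, %d]", n, p),
          class = "iplslasso_division_error")
  }
  widths <- rep(p %/% n, n)
  extra <- p %% n
  if (extra > 0) widths[seq_len(extra)] <- widths[seq_len(extra)] + 1L
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  structure(
    tibble(interval = seq_len(n), start = starts, end = ends, width = widths),
    p = p, n = n,
    class = c("interval_division", class(tibble()))
  )
}

interval_columns <- function(division, j) {
  seq.int(division$start[j], division$end[j])
}

#' Fit interval PLS member models
#'
#' Divides the spectrum into `n` equal-width intervals and fits one PLS
#' model per interval: the latent-variable count is selected by
#' cross-validation restricted to that interval's columns, the final member
#' is refit on the full calibration set at the selected count, and the
#' out-of-fold predictions at that count are stored as the member's
#' cross-validated outputs (the inputs of the Lasso fusion — never in-sample
#' fits). With `n = 1` this reduces exactly to the full-spectrum PLS model.
#'
#' @param cal A `spectra_set` with reference values (the calibration set).
#' @param n Interval count.
#' @param folds A `fold_scheme` over the calibration samples.
#' @param max_lv Maximum latent-variable count per member (default 20).
#' @return An object of class `ipls_model_set`: list with `division`,
#'   `models` (one `pls_model` per interval), `lv` (selected counts),
#'   `rmsecv` (per interval), `cv_outputs` (samples x n matrix),
#'   `best_index` (interval with minimum RMSECV, 1-based), `y`.
#' @export
fit_ipls <- function(cal, n, folds, max_lv = 20) {
  stopifnot(inherits(cal, "spectra_set"))
  if (is.null(cal$y)) {
    abort("calibration set has no reference values",
          class = "iplslasso_input_error")
  }
  division <- divide_intervals(n_wavelengths(cal), n)
  check_folds(folds, n_samples(cal))
  models <- vector("list", n)
  lv <- integer(n)
  rmsecv <- numeric(n)
  cv_outputs <- matrix(NA_real_, n_samples(cal), n)
  for (j in seq_len(n)) {
    cols <- interval_columns(division, j)
    Xj <- cal$X[, cols, drop = FALSE]
    cv <- cross_validate_lv(Xj, cal$y, max_lv = max_lv, folds = folds)
    lv[j] <- cv$selected
    rmsecv[j] <- cv$rmsecv[cv$selected]
    cv_outputs[, j] <- cv$cv_pred[, cv$selected]
    models[[j]] <- fit_pls(Xj, cal$y, n_lv = cv$selected, column_index = cols)
  }
  structure(
    list(division = division, models = models, lv = lv, rmsecv = rmsecv,
         cv_outputs = cv_outputs, best_index = which.min(rmsecv),
         y = cal$y, folds = folds, max_lv = max_lv),
    class = "ipls_model_set"
  )
}

#' @export
print.ipls_model_set <- function(x, ...) {
  n <- attr(x$division, "n")
  cat(sprintf("<ipls_model_set> %d interval(s), best interval %d/%d (RMSECV %.3f)\n",
              n, x$best_index, n, min(x$rmsecv)))
  invisible(x)
}

#' Member predictions on new spectra
#'
#' @param ims An `ipls_model_set`.
#' @param X Full-width spectral matrix or `spectra_set` sharing the
#'   calibration wavelength axis.
#' @return Numeric matrix (samples x n): column `j` holds member `j`'s
#'   predictions from its own interval columns.
#' @export
predict_members <- function(ims, X) {
  stopifnot(inherits(ims, "ipls_model_set"))
  if (inherits(X, "spectra_set")) X <- X$X
  X <- check_numeric_matrix(X)
  if (ncol(X) != attr(ims$division, "p")) {
    abort(sprintf("X has %d columns; the division expects %d",
                  ncol(X), attr(ims$division, "p")),
          class = "iplslasso_shape_error")
  }
  out <- vapply(seq_along(ims$models), function(j) {
    predict(ims$models[[j]], X[, interval_columns(ims$division, j), drop = FALSE])
  }, numeric(nrow(X)))
  matrix(out, nrow = nrow(X))
}

#' Summarize interval members
#'
#' @param x An `ipls_model_set`.
#' @param ... Unused.
#' @return A tibble with one row per interval: `interval`, `label`
#'   (`"k/n"`), `start`, `end`, `width`, `n_lv`, `rmsecv`, `best`.
#' @export
tidy.ipls_model_set <- function(x, ...) {
  n <- attr(x$division, "n")
  tibble(
    interval = x$division$interval,
    label = paste0(x$division$interval, "/", n),
    start = x$division$start,
    end = x$division$end,
    width = x$division$width,
    n_lv = x$lv,
    rmsecv = x$rmsecv,
    best = x$division$interval == x$best_index
  )
}

#' @rdname tidy.ipls_model_set
#' @export
glance.ipls_model_set <- function(x, ...) {
  tibble(n_intervals = attr(x$division, "n"),
         best_index = x$best_index,
         best_rmsecv = min(x$rmsecv),
         best_label = paste0(x$best_index, "/", attr(x$division, "n")))
}
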