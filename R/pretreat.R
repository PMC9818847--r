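# Spectral pretreatments: SNV, MSC and Savitzky-Golay first derivative.
# All operate row-wise on a samples-by-wavelengths matrix and preserve its
# dimensions.

#' Standard normal variate transform
#'
#' Each spectrum is centered to mean zero and scaled to unit standard
#' deviation, removing multiplicative and additive scatter on a per-sample
#' basis.
#'
#' @param X Numeric matrix (samples x wavelengths) or `spectra_set`.
#' @param denom_n_minus_1 Use the sample (n-1) standard deviation (default
#'   `TRUE`); set `FALSE` for the population (n) convention.
#' @return Object of the same type as `X` with each row standardized.
#' @export
snv <- function(X, denom_n_minus_1 = TRUE) {
  if (inherits(X, "spectra_set")) {
    out <- X
    out$X <- snv(X$X, denom_n_minus_1)
    return(out)
  }
  X <- check_numeric_matrix(X)
  m <- rowMeans(X)
  ss <- rowSums((X - m)^2)
  denom <- if (denom_n_minus_1) ncol(X) - 1L else ncol(X)
  s <- sqrt(ss / denom)
  if (any(s < 1e-12)) {
    abort(sprintf("constant spectrum in row(s): %s",
                  paste(which(s < 1e-12), collapse = ", ")),
          class = "iplslasso_degenerate_error")
  }
  (X - m) / s
}

#' Multiplicative scatter correction
#'
#' Each spectrum is regressed on a reference spectrum by ordinary least
#' squares (`row = b + a * reference`) and corrected as `(row - b) / a`,
#' removing additive offsets and multiplicative scaling relative to the
#' reference. The reference defaults to the mean spectrum of `X`.
#'
#' @param X Numeric matrix (samples x wavelengths) or `spectra_set`.
#' @param reference Optional reference spectrum; defaults to `colMeans(X)`.
#' @return A list with `X` (the corrected matrix or `spectra_set`) and
#'   `reference` (the spectrum used, to be reapplied to new data).
#' @export
msc <- function(X, reference = NULL) {
  if (inherits(X, "spectra_set")) {
    res <- msc(X$X, reference)
    out <- X
    out$X <- res$X
    return(list(X = out, reference = res$reference))
  }
  X <- check_numeric_matrix(X)
  if (is.null(reference)) reference <- colMeans(X)
  reference <- as.numeric(reference)
  stopifnot(length(reference) == ncol(X))
  rc <- reference - mean(reference)
  vr <- sum(rc^2)
  if (vr < 1e-12) {
    abort("reference spectrum is constant", class = "iplslasso_degenerate_error")
  }
  a <- as.vector(X %*% rc) / vr            # slope of row on reference
  b <- rowMeans(X) - a * mean(reference)
  if (any(abs(a) < 1e-12)) {
    abort(sprintf("non-correctable row(s) with near-zero slope: %s",
                  paste(which(abs(a) < 1e-12), collapse = ", ")),
          class = "iplslasso_degenerate_error")
  }
  list(X = (X - b) / a, reference = reference)
}

#' Savitzky-Golay first derivative
#'
#' Per-spectrum first derivative by local polynomial smoothing, in index
#' units (one column step). Edges are handled by evaluating the boundary
#' polynomial fits, so the column count is unchanged. The defaults (5-point
#' window, degree-2 polynomial) reproduce the derivative exactly on
#' polynomials up to degree 2.
#'
#' @param X Numeric matrix (samples x wavelengths) or `spectra_set`.
#' @param window Odd window length in points (default 5).
#' @param degree Polynomial degree (default 2), must be < `window`.
#' @param delta Column spacing used to scale the derivative (default 1 =
#'   per-index; pass the mean wavelength step for a per-nm derivative).
#' @return Object of the same type as `X`, differentiated row-wise.
#' @export
sg_first_derivative <- function(X, window = 5, degree = 2, delta = 1) {
  if (inherits(X, "spectra_set")) {
    out <- X
    out$X <- sg_first_derivative(X$X, window, degree, delta)
    return(out)
  }
  X <- check_numeric_matrix(X)
  if (window %% 2 != 1 || window <= degree || degree < 1) {
    abort("need odd `window` > `degree` >= 1", class = "iplslasso_param_error")
  }
  if (ncol(X) < window) {
    abort(sprintf("need at least %d columns for window %d", window, window),
          class = "iplslasso_param_error")
  }
  t(apply(X, 1, function(row) {
    signal::sgolayfilt(row, p = degree, n = window, m = 1, ts = delta)
  }))
}

#' Apply a named pretreatment
#'
#' Dispatches the pretreatment enum used throughout the calibration
#' protocol: `"none"`, `"snv"`, `"msc"` or `"d1st_sg"`.
#'
#' @param ds A `spectra_set`.
#' @param method One of `"none"`, `"snv"`, `"msc"`, `"d1st_sg"`.
#' @param msc_reference Optional stored MSC reference (for applying a fitted
#'   pretreatment to new spectra).
#' @param window,degree Savitzky-Golay parameters for `"d1st_sg"`.
#' @return A list with `ds` (pretreated `spectra_set`), `method` and
#'   `msc_reference` (non-`NULL` only for MSC).
#' @export
pretreat <- function(ds, method = c("none", "snv", "msc", "d1st_sg"),
                     msc_reference = NULL, window = 5, degree = 2) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "spectra_set"))
  ref <- NULL
  out <- switch(method,
    none = ds,
    snv = snv(ds),
    msc = {
      res <- msc(ds, reference = msc_reference)
      ref <- res$reference
      res$X
    },
    d1st_sg = sg_first_derivative(ds, window = window, degree = degree)
  )
  list(ds = out, method = method, msc_reference = ref)
}
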