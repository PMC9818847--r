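# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. Seeds must stay below 2^31 - 1 (R integers).
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round-half-up: round(68.5) in base R goes to even; the 2:1 split rule needs
# 0.5 to round up so that 103 samples give 69 calibration rows.
round_half_up <- function(x) floor(x + 0.5)

#' Build a cross-validation fold scheme
#'
#' Samples are shuffled once under `seed` and then cut into `k` contiguous
#' blocks of near-equal size, so every sample is held out exactly once. The
#' same scheme object is reused for latent-variable selection, member-model
#' cross-validation and Lasso tuning so that all stages see identical splits.
#'
#' @param n Number of samples.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the single shuffle.
#' @return An object of class `fold_scheme`: a list of integer index vectors,
#'   one per fold, with attributes `n`, `k` and `seed`.
#' @examples
#' make_folds(10, k = 5, seed = 1)
#' @export
make_folds <- function(n, k = 5, seed = 1) {
  stopifnot(n >= 2, k >= 2)
  if (k > n) {
    abort(sprintf("cannot build %d folds from %d samples", k, n),
          class = "iplslasso_fold_error")
  }
  idx <- with_local_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  folds <- split(idx, rep(seq_len(k), times = sizes))
  folds <- unname(lapply(folds, sort))
  structure(folds, n = n, k = k, seed = seed, class = "fold_scheme")
}

is_fold_scheme <- function(x) inherits(x, "fold_scheme")

check_folds <- function(folds, n) {
  if (!is_fold_scheme(folds)) {
    abort("`folds` must be created by make_folds()", class = "iplslasso_fold_error")
  }
  held <- sort(unlist(folds))
  if (!identical(held, seq_len(n))) {
    abort("fold scheme does not cover all samples exactly once",
          class = "iplslasso_fold_error")
  }
  invisible(folds)
}

# Minimum-norm least squares via SVD pseudoinverse (used by the unpenalized
# member stack when the design is rank deficient).
pinv_solve <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!all(keep)) {
    warn("rank-deficient stack; using minimum-norm least-squares solution")
  }
  d_inv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (d_inv * crossprod(sv$u, b))
}

check_numeric_matrix <- function(X, arg = "X") {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X) || !all(is.finite(X))) {
    abort(sprintf("`%s` must be a finite numeric matrix", arg),
          class = "iplslasso_input_error")
  }
  X
}
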