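# Shared fixture builders. Everything is generated in code at test time.

# Small random spectra_set with a linear X -> y link.
tiny_spectra <- function(n = 20, p = 12, seed = 1, noise = 0.1, meta = NULL) {
  withr_seed <- function(code) iplslasso:::with_local_seed(seed, code)
  withr_seed({
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p)
    y <- as.vector(X %*% beta) + rnorm(n, sd = noise)
    spectra_set(seq(550, 550 + p - 1), X, y = y, meta = meta)
  })
}

# A custom fold scheme from an explicit list of held-out index vectors.
manual_folds <- function(folds, n) {
  structure(lapply(folds, as.integer), n = n, k = length(folds), seed = NA,
            class = "fold_scheme")
}

# Explicit per-window polynomial-fit first derivative (oracle for the
# Savitzky-Golay filter, including its polynomial-fit edge handling).
polyfit_first_derivative <- function(x, window = 5, degree = 2) {
  p <- length(x)
  h <- (window - 1) / 2
  out <- numeric(p)
  for (t in seq_len(p)) {
    if (t <= h) {
      idx <- 1:window
    } else if (t > p - h) {
      idx <- (p - window + 1):p
    } else {
      idx <- (t - h):(t + h)
    }
    fit <- lm(x[idx] ~ poly(idx, degree, raw = TRUE))
    cf <- coef(fit)
    # derivative of the fitted polynomial evaluated at position t
    out[t] <- sum(cf[-1] * seq_len(degree) * t^(seq_len(degree) - 1))
  }
  out
}

ols_coefs <- function(X, y) {
  as.vector(coef(lm(y ~ X)))
}
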