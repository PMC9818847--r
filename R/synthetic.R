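# Synthetic egg cohorts and vis/SW-NIR-like semi-transmittance spectra with a
# known freshness-to-spectrum link, so every modeling stage can be validated
# end to end without measured egg spectra.

#' Simulation configuration
#'
#' Collects every knob of the synthetic generator. The defaults emulate the
#' study conditions: a 105-egg cohort sampled in batches over a 13-day
#' storage trajectory, weights around 57.53 g (SD 4.095), Haugh units
#' declining from ~85 to ~62 and clipped to [56, 91], spectra on a
#' 550-985 nm axis with 2041 points carrying absorption valleys near 645,
#' 770, 880 and 970 nm, multiplicative/additive scatter between replicates,
#' and three replicate readings per egg.
#'
#' @param n_eggs Number of eggs (default 105).
#' @param days Sampled storage days; eggs are assigned to days in equal
#'   batches (default `c(1, 3, 5, 7, 9, 11, 13)`).
#' @param seed Integer seed; the generator is bitwise-reproducible for a
#'   fixed seed.
#' @param wl_range Wavelength range in nm (default `c(550, 985)`).
#' @param n_wavelengths Grid size (default 2041).
#' @param band_centers Absorption-valley centers in nm.
#' @param band_widths Gaussian valley widths (nm).
#' @param band_depths Valley depths (%T) at the reference freshness
#'   `hu_ref`.
#' @param band_hu_coef Depth increase (%T) per HU lost below `hu_ref` — the
#'   planted freshness signal.
#' @param band_day_coef Depth increase (%T) per storage day, independent of
#'   HU (partially decoupled storage dynamics).
#' @param band_jitter_sd Per-egg, per-band depth jitter SD (%T): structured
#'   interference that does not average out across wavelengths and sets the
#'   attainable calibration error.
#' @param hu_ref Reference HU at which `band_depths` apply (default 85).
#' @param hu_start_mean,hu_start_sd Day-1 HU distribution.
#' @param hu_noise_sd Egg-level HU noise around the day trajectory.
#' @param hu_range Clipping range for HU (default `c(56, 91)`).
#' @param weight_mean,weight_sd,weight_range Arrival-weight distribution
#'   (g), truncated to `weight_range`; the underlying mean is shifted so
#'   the truncated mean equals `weight_mean` exactly.
#' @param scatter_sd SD of the log multiplicative replicate scatter.
#' @param offset_sd SD of the additive replicate offset (%T).
#' @param noise_sd SD of the iid measurement noise (%T).
#' @param replicates Replicate readings per egg (default 3).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_eggs = 105,
                       days = c(1, 3, 5, 7, 9, 11, 13),
                       seed = 1,
                       wl_range = c(550, 985),
                       n_wavelengths = 2041,
                       band_centers = c(645, 770, 880, 970),
                       band_widths = c(22, 18, 25, 20),
                       band_depths = c(4, 5, 3, 4.5),
                       band_hu_coef = c(0.035, 0.06, 0.03, 0.05),
                       band_day_coef = c(0.02, 0.05, 0.02, 0.06),
                       band_jitter_sd = c(0.7, 1.05, 0.7, 0.9),
                       hu_ref = 85,
                       hu_start_mean = 85, hu_start_sd = 4,
                       hu_noise_sd = 2,
                       hu_range = c(56, 91),
                       weight_mean = 57.53, weight_sd = 4.095,
                       weight_range = c(49.095, 69.514),
                       scatter_sd = 0.08, offset_sd = 0.6, noise_sd = 0.25,
                       replicates = 3) {
  cfg <- as.list(environment())
  nb <- length(cfg$band_centers)
  stopifnot(
    cfg$n_eggs >= 1, length(cfg$days) >= 1,
    cfg$n_wavelengths >= 2, cfg$wl_range[1] < cfg$wl_range[2],
    lengths(cfg[c("band_widths", "band_depths", "band_hu_coef",
                  "band_day_coef", "band_jitter_sd")]) == nb,
    cfg$scatter_sd >= 0, cfg$offset_sd >= 0, cfg$noise_sd >= 0,
    cfg$band_jitter_sd >= 0, cfg$replicates >= 1,
    cfg$hu_range[1] < cfg$hu_range[2],
    cfg$weight_range[1] < cfg$weight_range[2]
  )
  if (cfg$weight_mean <= cfg$weight_range[1] ||
      cfg$weight_mean >= cfg$weight_range[2]) {
    abort("weight_mean must lie inside weight_range",
          class = "iplslasso_config_error")
  }
  structure(cfg, class = "sim_config")
}

# Truncated-normal sampler by inverse CDF, with the underlying mean shifted
# (uniroot on the closed-form truncated mean) so the truncated distribution
# has mean `target_mean` exactly.
rtruncnorm_mean <- function(n, target_mean, sd, lo, hi) {
  trunc_mean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - target_mean,
                       lower = lo, upper = hi, tol = 1e-10)$root
  u <- runif(n, pnorm((lo - mu) / sd), pnorm((hi - mu) / sd))
  mu + sd * qnorm(u)
}

# Mean HU decline relative to day 1: gentle to day 7, sharp drop to day 9,
# then a gentler continued decline.
hu_trajectory_delta <- function(day) {
  knots_x <- c(1, 7, 9, 13)
  knots_y <- c(0, -6, -15, -23)
  stats::approx(knots_x, knots_y, xout = pmin(pmax(day, 1), 13), rule = 2)$y
}

#' Generate a synthetic egg cohort
#'
#' Draws per-egg morphology and freshness records along the storage
#' trajectory: arrival weights from a truncated normal with mean 57.53 g,
#' Haugh units starting near 85 and declining (gently to day 7, sharply to
#' day 9), weight loss rate increasing and yolk coefficient decreasing with
#' storage day. The albumen height is back-solved from the Haugh-unit
#' formula so `haugh_unit(albumen_height_mm, weight_g)` reproduces the
#' assigned HU exactly.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with one row per egg: `egg_id`, `day`,
#'   `arrival_weight_g`, `weight_g`, `albumen_height_mm`, `yolk_height_mm`,
#'   `yolk_diameter_mm`, `long_axis_mm`, `short_axis_mm`, `hu`.
#' @export
generate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, {
    n <- cfg$n_eggs
    day <- sort(rep(cfg$days, length.out = n))   # equal batches per day
    arrival <- rtruncnorm_mean(n, cfg$weight_mean, cfg$weight_sd,
                               cfg$weight_range[1], cfg$weight_range[2])
    hu <- cfg$hu_start_mean + rnorm(n, 0, cfg$hu_start_sd) +
      hu_trajectory_delta(day) + rnorm(n, 0, cfg$hu_noise_sd)
    hu <- pmin(pmax(hu, cfg$hu_range[1]), cfg$hu_range[2])
    wlr <- pmax(0, 0.5 * day * (1 + rnorm(n, 0, 0.15)))
    weight <- arrival * (1 - wlr / 100)
    albumen <- albumen_height_for_hu(hu, weight)
    yolk_diam <- rnorm(n, 38 + 0.25 * day, 1.5)
    yc <- pmax(0.05, 0.44 - 0.012 * day + rnorm(n, 0, 0.02))
    short <- pmin(pmax(rnorm(n, 43.2, 1.3), 40.24), 46.16)
    si <- pmin(pmax(rnorm(n, 1.273, 0.037), 1.16), 1.39)
    tibble(
      egg_id = sprintf("egg%03d", seq_len(n)),
      day = day,
      arrival_weight_g = arrival,
      weight_g = weight,
      albumen_height_mm = albumen,
      yolk_height_mm = yc * yolk_diam,
      yolk_diameter_mm = yolk_diam,
      long_axis_mm = short * si,
      short_axis_mm = short,
      hu = hu
    )
  })
}

#' Generate synthetic semi-transmittance spectra for a cohort
#'
#' Each egg's clean spectrum is a smooth transmittance baseline (attenuated
#' with storage day) minus Gaussian absorption valleys at the configured
#' band centers; valley depths are affine in the egg's Haugh unit and
#' storage day plus a per-egg jitter. Every replicate reading is
#' `a * clean + b + noise` with log-normal multiplicative scatter `a`,
#' normal additive offset `b` and iid measurement noise; negative
#' transmittances are clipped at zero with a warning.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param cfg The matching [sim_config()].
#' @return A `spectra_set` with `replicates` rows per egg, reference values
#'   set to the eggs' HU and metadata columns `egg_id`, `replicate`, `day`,
#'   `weight_g`.
#' @export
generate_spectra <- function(cohort, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"), nrow(cohort) >= 1)
  wl <- seq(cfg$wl_range[1], cfg$wl_range[2], length.out = cfg$n_wavelengths)
  baseline <- 25 * exp(-((wl - 760) / 160)^2) + 6
  bands <- vapply(seq_along(cfg$band_centers), function(b) {
    exp(-((wl - cfg$band_centers[b]) / cfg$band_widths[b])^2)
  }, numeric(length(wl)))
  with_local_seed(cfg$seed + 1, {
    n_eggs <- nrow(cohort)
    n_rows <- n_eggs * cfg$replicates
    X <- matrix(0, n_rows, length(wl))
    jitter <- matrix(rnorm(n_eggs * length(cfg$band_centers), 0,
                           rep(cfg$band_jitter_sd, each = n_eggs)),
                     n_eggs)
    clipped <- 0L
    row <- 0L
    for (i in seq_len(n_eggs)) {
      depths <- cfg$band_depths +
        cfg$band_hu_coef * (cfg$hu_ref - cohort$hu[i]) +
        cfg$band_day_coef * cohort$day[i] +
        jitter[i, ]
      clean <- (1 - 0.012 * cohort$day[i]) * baseline -
        as.vector(bands %*% pmax(depths, 0))
      for (r in seq_len(cfg$replicates)) {
        row <- row + 1L
        a <- exp(rnorm(1, 0, cfg$scatter_sd))
        b <- rnorm(1, 0, cfg$offset_sd)
        spec <- a * clean + b + rnorm(length(wl), 0, cfg$noise_sd)
        neg <- spec < 0
        if (any(neg)) {
          clipped <- clipped + sum(neg)
          spec[neg] <- 0
        }
        X[row, ] <- spec
      }
    }
    if (clipped > 0) {
      warn(sprintf("%d negative transmittance value(s) clipped to 0", clipped))
    }
    rep_idx <- rep(seq_len(cfg$replicates), times = n_eggs)
    egg_idx <- rep(seq_len(n_eggs), each = cfg$replicates)
    spectra_set(
      wl, X,
      y = cohort$hu[egg_idx],
      sample_ids = paste0(cohort$egg_id[egg_idx], "_r", rep_idx),
      meta = tibble(egg_id = cohort$egg_id[egg_idx],
                    replicate = rep_idx,
                    day = cohort$day[egg_idx],
                    weight_g = cohort$weight_g[egg_idx])
    )
  })
}

#' Simulate a complete spectral study
#'
#' Convenience wrapper: cohort, replicate spectra, replicate averaging.
#'
#' @param cfg A [sim_config()].
#' @param average Average the replicate spectra per egg (default `TRUE`).
#' @return A list with `cohort` (tibble) and `spectra` (`spectra_set`).
#' @export
simulate_study <- function(cfg = sim_config(), average = TRUE) {
  cohort <- generate_cohort(cfg)
  spectra <- generate_spectra(cohort, cfg)
  if (average) spectra <- average_replicates(spectra, "egg_id")
  list(cohort = cohort, spectra = spectra)
}

#' Plant a known interval-confined signal
#'
#' Oracle-construction helper for interval-selection tests: all columns are
#' independent standard-normal noise, and the response is a linear function
#' of columns inside the designated intervals only, plus optional response
#' noise. Within each signal interval the contributing columns form one
#' contiguous central block covering a fraction `span` of the interval, and
#' they share a latent factor (band value = factor + independent column
#' noise) — emulating an absorption band whose wavelengths rise and fall
#' together, rather than signal smeared over independent columns. The
#' response adds each block's column average, so `y` is an exact linear
#' function of the signal columns and each interval contributes roughly
#' unit response variance.
#'
#' @param p Variable count.
#' @param n Interval count.
#' @param signal_intervals 1-based interval indices carrying signal.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param noise_sd SD of the additive response noise (default 0.5).
#' @param span Fraction of each signal interval's columns carrying the
#'   band-like signal (default 0.2; at least one column).
#' @param band_col_noise SD of the independent per-column noise around the
#'   band's shared factor (default 0.5; the factor has SD 1).
#' @return A `spectra_set` (wavelength axis `1..p`) whose `y` depends only
#'   on columns inside the signal intervals; the division is attached as
#'   attribute `division`.
#' @export
plant_interval_signal <- function(p, n, signal_intervals, n_samples,
                                  seed = 1, noise_sd = 0.5, span = 0.2,
                                  band_col_noise = 0.5) {
  division <- divide_intervals(p, n)
  signal_intervals <- as.integer(signal_intervals)
  if (length(signal_intervals) < 1 ||
      !all(signal_intervals %in% seq_len(n))) {
    abort("signal_intervals must be a non-empty subset of 1..n",
          class = "iplslasso_config_error")
  }
  stopifnot(span > 0, span <= 1)
  with_local_seed(seed, {
    X <- matrix(rnorm(n_samples * p), n_samples, p)
    y <- rnorm(n_samples, 0, noise_sd)
    for (j in signal_intervals) {
      cols <- interval_columns(division, j)
      m <- max(1L, ceiling(span * length(cols)))
      offset <- (length(cols) - m) %/% 2
      band <- cols[offset + seq_len(m)]
      f <- rnorm(n_samples)
      X[, band] <- f + band_col_noise *
        matrix(rnorm(n_samples * m), n_samples, m)
      y <- y + rowMeans(X[, band, drop = FALSE])
    }
    ds <- spectra_set(seq_len(p), X, y = y)
    attr(ds, "division") <- division
    ds
  })
}
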