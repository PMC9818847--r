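test_that("cohort statistics match the configured study conditions", {
  cfg <- sim_config(n_eggs = 10000, seed = 42)
  cohort <- generate_cohort(cfg)
  expect_lt(abs(mean(cohort$arrival_weight_g) - 57.53), 0.15)
  expect_true(all(cohort$arrival_weight_g >= 49.095 &
                    cohort$arrival_weight_g <= 69.514))
  expect_true(all(cohort$hu >= 56 & cohort$hu <= 91))
  # the albumen height was back-solved, so the formula returns the stored HU
  expect_equal(haugh_unit(cohort$albumen_height_mm, cohort$weight_g),
               cohort$hu, tolerance = 1e-9)
  # freshness dynamics: WLR increases, yolk coefficient decreases with day
  by_day <- dplyr::summarise(
    dplyr::group_by(freshness_indicators(cohort), day),
    hu = mean(hu), wlr = mean(wlr_pct), yc = mean(yolk_coef))
  expect_true(all(diff(by_day$wlr) > 0))
  expect_true(all(diff(by_day$yc) < 0))
  expect_true(all(diff(by_day$hu) < 0))
})

test_that("generation is bitwise reproducible for a fixed seed", {
  cfg <- sim_config(n_eggs = 12, seed = 7, n_wavelengths = 301)
  a <- simulate_study(cfg, average = FALSE)
  b <- simulate_study(cfg, average = FALSE)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$spectra$X, b$spectra$X)
})

test_that("spectra are finite, non-negative and carry the freshness signal", {
  cfg <- sim_config(n_eggs = 14, seed = 3, n_wavelengths = 501)
  st <- simulate_study(cfg, average = FALSE)
  expect_true(all(is.finite(st$spectra$X)))
  expect_true(all(st$spectra$X >= 0))
  expect_equal(n_samples(st$spectra), 14 * 3)
})

test_that("with no scatter or jitter, eggs differing only in HU differ only near bands", {
  # widen the axis so a region far from every absorption band exists
  cfg <- sim_config(n_eggs = 2, days = 1, seed = 5, wl_range = c(400, 1200),
                    n_wavelengths = 1201,
                    scatter_sd = 0, offset_sd = 0, noise_sd = 0,
                    band_jitter_sd = rep(0, 4), replicates = 1,
                    hu_noise_sd = 0)
  cohort <- generate_cohort(cfg)
  cohort$hu <- c(60, 88)
  cohort$weight_g <- rep(57, 2)
  cohort$day <- c(1, 1)
  sp <- generate_spectra(cohort, cfg)
  d <- abs(sp$X[1, ] - sp$X[2, ])
  wl <- sp$wavelengths
  near_band <- rowSums(vapply(seq_along(cfg$band_centers), function(b) {
    abs(wl - cfg$band_centers[b]) < 6 * cfg$band_widths[b]
  }, logical(length(wl)))) > 0
  expect_gt(sum(!near_band), 0)
  expect_gt(max(d[near_band]), 0.1)
  expect_lt(max(d[!near_band]), 1e-8)
})

test_that("SNV removes the planted replicate scatter", {
  cfg <- sim_config(n_eggs = 1, days = 1, seed = 6, n_wavelengths = 801,
                    noise_sd = 0, band_jitter_sd = rep(0, 4),
                    scatter_sd = 0.2, offset_sd = 1)
  st <- simulate_study(cfg, average = FALSE)
  Xs <- snv(st$spectra$X)
  expect_lt(max(abs(Xs[1, ] - Xs[2, ])), 1e-8)
  expect_lt(max(abs(Xs[1, ] - Xs[3, ])), 1e-8)
})

test_that("planted interval signal drives members as designed", {
  ds <- plant_interval_signal(p = 60, n = 6, signal_intervals = 2,
                              n_samples = 80, seed = 11, noise_sd = 0)
  folds <- make_folds(80, 5, seed = 1)
  ims <- fit_ipls(ds, n = 6, folds = folds, max_lv = 10)
  expect_equal(ims$best_index, 2)
  expect_lt(ims$rmsecv[2], 1e-6)
  expect_error(plant_interval_signal(60, 6, integer(0), 10),
               class = "iplslasso_config_error")
  expect_error(plant_interval_signal(60, 6, 7, 10),
               class = "iplslasso_config_error")
})

test_that("more response noise degrades the fusion on average", {
  rmsep_at <- function(noise_sd) {
    vapply(1:10, function(seed) {
      ds <- plant_interval_signal(p = 80, n = 4, signal_intervals = 2,
                                  n_samples = 75, seed = seed,
                                  noise_sd = noise_sd)
      sp <- split_calibration(ds, seed = seed)
      folds <- make_folds(n_samples(sp$calibration), 5, seed = seed)
      fm <- fit_ipls_lasso(sp$calibration, n = 4, folds = folds, max_lv = 4)
      regression_metrics(sp$prediction$y, predict(fm, sp$prediction$X))$rmse
    }, numeric(1))
  }
  expect_lt(mean(rmsep_at(0.2)), mean(rmsep_at(1.5)))
})
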