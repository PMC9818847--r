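# Shared small planted-signal problem for the fusion stage.
fusion_problem <- function(seed, n_samples = 90, p = 200, n = 10,
                           signal = c(3, 7), noise_sd = 0.5) {
  ds <- plant_interval_signal(p = p, n = n, signal_intervals = signal,
                              n_samples = n_samples, seed = seed,
                              noise_sd = noise_sd)
  sp <- split_calibration(ds, ratio = c(2, 1), seed = seed)
  folds <- make_folds(n_samples(sp$calibration), 5, seed = seed)
  list(cal = sp$calibration, pred = sp$prediction, folds = folds)
}

test_that("a one-interval fusion is exactly the full-spectrum PLS model", {
  ds <- tiny_spectra(n = 30, p = 25, seed = 1, noise = 0.5)
  folds <- make_folds(30, 5, seed = 1)
  fm <- fit_ipls_lasso(ds, n = 1, folds = folds, max_lv = 8)
  cv <- cross_validate_lv(ds$X, ds$y, max_lv = 8, folds = folds)
  ref <- fit_pls(ds$X, ds$y, n_lv = cv$selected)
  expect_identical(predict(fm, ds$X), predict(ref, ds$X))
  expect_equal(fm$selected, 1L)
  expect_equal(fm$label, "1/1")
})

test_that("the fusion keeps the planted member models across seeds", {
  hits <- 0
  for (seed in 1:20) {
    prob <- fusion_problem(seed)
    fm <- fit_ipls_lasso(prob$cal, n = 10, folds = prob$folds, max_lv = 6)
    hits <- hits + all(c(3, 7) %in% fm$selected)
  }
  expect_gte(hits, 18)
})

test_that("fusion reports use the selected/total label notation", {
  prob <- fusion_problem(1)
  fm <- fit_ipls_lasso(prob$cal, n = 10, folds = prob$folds, max_lv = 6)
  expect_equal(fm$label, paste0(length(fm$selected), "/10"))
  tab <- tidy(fm)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$selected, tab$estimate != 0)
  expect_equal(sum(tab$estimate == 0), 10 - length(fm$selected))
})

test_that("fusion predictions scale linearly with the response", {
  ds <- plant_interval_signal(p = 120, n = 6, signal_intervals = 4,
                              n_samples = 50, seed = 9, noise_sd = 0.3)
  folds <- make_folds(50, 5, seed = 1)
  fm1 <- fit_ipls_lasso(ds, n = 6, folds = folds, max_lv = 4)
  ds2 <- ds
  ds2$y <- 3 * ds$y
  fm2 <- fit_ipls_lasso(ds2, n = 6, folds = folds, max_lv = 4)
  expect_equal(predict(fm2, ds$X), 3 * predict(fm1, ds$X), tolerance = 1e-6)
})

test_that("selection is reproducible under fixed seeds and folds", {
  prob <- fusion_problem(5)
  fm1 <- fit_ipls_lasso(prob$cal, n = 10, folds = prob$folds, max_lv = 6)
  fm2 <- fit_ipls_lasso(prob$cal, n = 10, folds = prob$folds, max_lv = 6)
  expect_identical(fm1$selected, fm2$selected)
  expect_identical(fm1$beta, fm2$beta)
})

test_that("the division sweep table has one coherent row per division", {
  prob <- fusion_problem(3, n_samples = 60, p = 90, n = 6, signal = 3)
  sw <- sweep_divisions(prob$cal, prob$pred, n_max = 6, folds = prob$folds,
                        max_lv = 4)
  expect_equal(sw$n, 1:6)
  expect_true(all(sw$n_selected <= sw$n))
  # the n = 1 row equals the plain PLS metrics
  base <- fit_pls_baseline(prob$cal, prob$pred, prob$folds, max_lv = 4)
  expect_equal(sw$rmsecv[1], base$metrics$rmsecv, tolerance = 1e-10)
  expect_equal(sw$rmsep[1], base$metrics$rmsep, tolerance = 1e-10)
  best_n <- attr(sw, "best_n")
  expect_true(best_n %in% 1:6)
  expect_lte(sw$rmsecv[best_n], min(sw$rmsecv) * 1.05)
})

test_that("fusion beats the best single member on average", {
  diffs <- vapply(1:10, function(seed) {
    prob <- fusion_problem(seed, n_samples = 90, p = 120, n = 6,
                           signal = c(2, 5))
    fm <- fit_ipls_lasso(prob$cal, n = 6, folds = prob$folds, max_lv = 4)
    fusion_rmsep <- regression_metrics(prob$pred$y,
                                       predict(fm, prob$pred$X))$rmse
    ims <- fm$members
    member_rmsep <- regression_metrics(
      prob$pred$y, predict_members(ims, prob$pred$X)[, ims$best_index])$rmse
    member_rmsep - fusion_rmsep
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("PLS-s1 reduces to known models at the selection extremes", {
  ds <- tiny_spectra(n = 30, p = 24, seed = 2, noise = 0.5)
  folds <- make_folds(30, 5, seed = 1)
  ims <- fit_ipls(ds, n = 4, folds = folds, max_lv = 6)
  sp <- split_calibration(tiny_spectra(n = 45, p = 24, seed = 3, noise = 0.5),
                          seed = 1)
  folds_cal <- make_folds(n_samples(sp$calibration), 5, seed = 1)
  ims_cal <- fit_ipls(sp$calibration, n = 4, folds = folds_cal, max_lv = 6)

  # all intervals selected -> identical to the full-spectrum PLS baseline
  all_sel <- structure(list(selected = 1:4, members = ims_cal),
                       class = "fusion_model")
  s1 <- fit_pls_s1(sp$calibration, sp$prediction, all_sel, folds_cal,
                   max_lv = 6)
  base <- fit_pls_baseline(sp$calibration, sp$prediction, folds_cal,
                           max_lv = 6)
  expect_identical(s1$metrics$rmsep, base$metrics$rmsep)
  expect_identical(unname(s1$model$B), unname(base$model$B))

  # a single selected interval -> that interval's member model
  one_sel <- structure(list(selected = 2L, members = ims_cal),
                       class = "fusion_model")
  s1_one <- fit_pls_s1(sp$calibration, sp$prediction, one_sel, folds_cal,
                       max_lv = 6)
  expect_equal(unname(s1_one$model$B), unname(ims_cal$models[[2]]$B))

  empty_sel <- structure(list(selected = integer(0), members = ims_cal),
                         class = "fusion_model")
  expect_error(fit_pls_s1(sp$calibration, sp$prediction, empty_sel,
                          folds_cal), class = "iplslasso_selection_error")
})

test_that("the unpenalized stack is outperformed by the lasso fusion", {
  # member-heavy regime as in the study: ~17 stack coefficients estimated
  # from 60 calibration rows, where unpenalized stacking overfits
  deltas <- vapply(1:10, function(seed) {
    prob <- fusion_problem(seed, n_samples = 90, p = 160, n = 16,
                           signal = c(3, 7))
    fm <- fit_ipls_lasso(prob$cal, n = 16, folds = prob$folds, max_lv = 4)
    s2 <- fit_pls_s2(prob$cal, prob$pred, fm$members)
    fusion_rmsep <- regression_metrics(prob$pred$y,
                                       predict(fm, prob$pred$X))$rmse
    s2$metrics$rmsep - fusion_rmsep
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("the stack resolves duplicated members deterministically", {
  # two intervals with identical columns -> identical members -> the stack
  # design is rank deficient and falls back to the minimum-norm solution
  half <- iplslasso:::with_local_seed(6, matrix(rnorm(30 * 10), 30, 10))
  y <- as.vector(half %*% rnorm(10)) + rnorm(30, sd = 0.3)
  ds <- spectra_set(seq_len(20), cbind(half, half), y = y)
  pred_half <- iplslasso:::with_local_seed(7, matrix(rnorm(10 * 10), 10, 10))
  pred_ds <- spectra_set(seq_len(20), cbind(pred_half, pred_half),
                         y = as.vector(pred_half %*% rnorm(10)))
  folds <- make_folds(30, 5, seed = 1)
  ims <- fit_ipls(ds, n = 2, folds = folds, max_lv = 4)
  expect_equal(ims$cv_outputs[, 1], ims$cv_outputs[, 2], tolerance = 1e-8)
  expect_warning(s2 <- fit_pls_s2(ds, pred_ds, ims), "minimum-norm")
  expect_true(all(is.finite(s2$coef)))
  # redistribution between the duplicated members leaves predictions alone
  Zp <- cbind(1, predict_members(ims, pred_ds$X))
  shift <- c(0, 0.3, -0.3)
  expect_equal(as.vector(Zp %*% s2$coef),
               as.vector(Zp %*% (s2$coef + shift)), tolerance = 1e-6)
})
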