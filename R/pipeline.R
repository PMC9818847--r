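# End-to-end pipeline: simulate -> fit -> predict. These functions are the
# programmatic form of the command-line entry points (inst/cli/iplslasso.R is
# a thin wrapper over them). Every run writes a manifest (configuration,
# seeds, package version) so two runs with equal manifests produce equal
# reports.

fit_defaults <- function() {
  list(
    group_key = "egg_id",    # replicate-averaging key ("" to skip)
    crop = NULL,             # c(lo, hi) nm, or NULL to keep the full axis
    outlier_alpha = 0.05,
    split_ratio = c(2, 1),
    split_seed = 42,
    fold_k = 5,
    fold_seed = 42,
    max_lv = 20,
    n_max = 40,
    cv_margin = 0.05,
    pretreatment = "none"    # pretreatment used for the interval stages
  )
}

load_config <- function(config) {
  if (is.null(config)) return(list())
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

merge_config <- function(defaults, config) {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown configuration field(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "iplslasso_schema_error")
  }
  utils::modifyList(defaults, config)
}

write_manifest <- function(path, kind, config) {
  manifest <- list(
    kind = kind,
    package = "iplslasso",
    version = as.character(utils::packageVersion("iplslasso")),
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Simulate a dataset to disk
#'
#' Generates a synthetic cohort and its replicate spectra and writes them in
#' the package's CSV dialect: `spectra.csv` (id + wavelengths header),
#' `reference.csv` (`id,HU,egg_id,replicate,day,weight_g`), `cohort.csv`
#' and `manifest.json` recording every generator parameter and the seed.
#'
#' @param config A [sim_config()], a list of `sim_config` arguments, or a
#'   path to a YAML file of them; `NULL` for the defaults.
#' @param out_dir Output directory (created if needed).
#' @return The output paths, invisibly.
#' @export
run_simulate <- function(config = NULL, out_dir) {
  cfg <- if (inherits(config, "sim_config")) {
    config
  } else {
    args <- load_config(config)
    bad <- setdiff(names(args), names(formals(sim_config)))
    if (length(bad)) {
      abort(sprintf("unknown simulation field(s): %s",
                    paste(bad, collapse = ", ")),
            class = "iplslasso_schema_error")
    }
    do.call(sim_config, args)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(cfg)
  spectra <- generate_spectra(cohort, cfg)
  paths <- list(
    spectra = file.path(out_dir, "spectra.csv"),
    reference = file.path(out_dir, "reference.csv"),
    cohort = file.path(out_dir, "cohort.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_spectra(spectra, paths$spectra, reference_path = paths$reference)
  readr::write_csv(cohort, paths$cohort)
  write_manifest(paths$manifest, "simulate", unclass(cfg))
  invisible(paths)
}

#' Run the full calibration protocol
#'
#' Executes the whole modeling protocol on a spectra + reference pair:
#' replicate averaging, outlier removal, 2:1 calibration/prediction split,
#' the four-way pretreatment comparison for the full-spectrum PLS baseline,
#' the iPLS-Lasso division sweep with the plain-iPLS and stacked
#' (PLS-s1/PLS-s2) comparators, and a JSON model bundle that
#' [run_predict()] can reload.
#'
#' @param spectra_path,reference_path Input CSVs in the package dialect.
#' @param out_dir Output directory.
#' @param config Named list (or YAML path) overriding the protocol knobs:
#'   `group_key`, `crop`, `outlier_alpha`, `split_ratio`, `split_seed`,
#'   `fold_k`, `fold_seed`, `max_lv`, `n_max`, `cv_margin`, `pretreatment`.
#' @return A list of class `fit_report` with the report tables
#'   (`pretreatments`, `sweep`, `models`), the flagged `outliers`, the
#'   fitted objects and the output paths.
#' @export
run_fit <- function(spectra_path, reference_path, out_dir, config = NULL) {
  cfg <- merge_config(fit_defaults(), load_config(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_spectra(spectra_path, reference_path)
  if (!is.null(cfg$crop)) ds <- crop_wavelengths(ds, cfg$crop[1], cfg$crop[2])
  if (nzchar(cfg$group_key) && !is.null(ds$meta) &&
      cfg$group_key %in% names(ds$meta)) {
    ds <- average_replicates(ds, cfg$group_key)
  }
  flags <- detect_outliers(ds, alpha = cfg$outlier_alpha)
  if (nrow(flags) > 0) ds <- remove_outliers(ds, flags)
  split <- split_calibration(ds, ratio = cfg$split_ratio, seed = cfg$split_seed)
  cal <- split$calibration
  pred <- split$prediction
  folds <- make_folds(n_samples(cal), k = cfg$fold_k, seed = cfg$fold_seed)

  # Pretreatment comparison for the full-spectrum PLS baseline
  pre_rows <- lapply(c("none", "snv", "msc", "d1st_sg"), function(method) {
    tr_cal <- pretreat(cal, method)
    tr_pred <- pretreat(pred, method, msc_reference = tr_cal$msc_reference)
    base <- fit_pls_baseline(tr_cal$ds, tr_pred$ds, folds, max_lv = cfg$max_lv)
    dplyr::bind_cols(tibble(pretreatment = method), base$metrics)
  })
  pretreatments <- dplyr::bind_rows(pre_rows)

  # Interval stages on the configured pretreatment
  tr_cal <- pretreat(cal, cfg$pretreatment)
  tr_pred <- pretreat(pred, cfg$pretreatment,
                      msc_reference = tr_cal$msc_reference)
  cal_m <- tr_cal$ds
  pred_m <- tr_pred$ds
  sweep <- sweep_divisions(cal_m, pred_m, n_max = cfg$n_max, folds = folds,
                           max_lv = cfg$max_lv, cv_margin = cfg$cv_margin,
                           keep_models = TRUE)
  best <- attr(sweep, "best_model")
  models_all <- attr(sweep, "models")

  # Best single interval member over all divisions >= 2 (the plain iPLS row)
  ipls_best <- NULL
  for (n in seq_len(cfg$n_max)[-1]) {
    ims <- models_all[[n]]$members
    if (is.null(ipls_best) || min(ims$rmsecv) < ipls_best$rmsecv) {
      j <- ims$best_index
      pm <- regression_metrics(pred_m$y,
                               predict_members(ims, pred_m$X)[, j])
      cm <- regression_metrics(cal_m$y, ims$cv_outputs[, j])
      ipls_best <- list(n = n, interval = j, rmsecv = min(ims$rmsecv),
                        metrics = tibble(n_lv = ims$lv[j],
                                         rmsecv = cm$rmse, r_cv = cm$r,
                                         bias_cv = cm$bias, rmsep = pm$rmse,
                                         r_p = pm$r, bias_p = pm$bias))
    }
  }

  base <- fit_pls_baseline(cal_m, pred_m, folds, max_lv = cfg$max_lv)
  s1 <- fit_pls_s1(cal_m, pred_m, best, folds, max_lv = cfg$max_lv)
  s2 <- fit_pls_s2(cal_m, pred_m, best$members)
  best_row <- sweep[sweep$n == attr(sweep, "best_n"), ]
  models <- dplyr::bind_rows(
    dplyr::bind_cols(tibble(model = "PLS", selected = "1/1"),
                     base$metrics[, -1]),
    if (!is.null(ipls_best)) dplyr::bind_cols(
      tibble(model = "iPLS",
             selected = paste0(ipls_best$interval, "/", ipls_best$n)),
      ipls_best$metrics[, -1]),
    dplyr::bind_cols(tibble(model = paste0("iPLS-L", best_row$n),
                            selected = best_row$label),
                     best_row[, c("rmsecv", "r_cv", "bias_cv",
                                  "rmsep", "r_p", "bias_p")]),
    dplyr::bind_cols(tibble(model = "PLS-s1", selected = best_row$label),
                     s1$metrics[, -1]),
    dplyr::bind_cols(tibble(model = "PLS-s2",
                            selected = paste0(best_row$n, "/", best_row$n)),
                     s2$metrics)
  )

  paths <- list(
    pretreatments = file.path(out_dir, "pretreatments.csv"),
    sweep = file.path(out_dir, "sweep.csv"),
    models = file.path(out_dir, "models.csv"),
    outliers = file.path(out_dir, "outliers.csv"),
    bundle = file.path(out_dir, "bundle.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(pretreatments, paths$pretreatments)
  readr::write_csv(as_tibble(sweep), paths$sweep)
  readr::write_csv(models, paths$models)
  readr::write_csv(flags, paths$outliers)
  write_bundle(best, tr_cal, cal_m$wavelengths, cfg, paths$bundle)
  write_manifest(paths$manifest, "fit", cfg)
  structure(
    list(pretreatments = pretreatments, sweep = sweep, models = models,
         outliers = flags, split = split, fusion = best,
         pls = base, pls_s1 = s1, pls_s2 = s2, config = cfg, paths = paths),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat("<fit_report>\n")
  cat(sprintf("  outliers removed: %d\n", length(unique(x$outliers$sample_id))))
  cat(sprintf("  recommended division: n = %d (%s members)\n",
              attr(x$sweep, "best_n"), x$fusion$label))
  print(x$models)
  invisible(x)
}

# Serialize the fusion model (plus pretreatment state) to JSON with full
# numeric precision, so reloaded predictions are bit-identical.
write_bundle <- function(fusion, tr_cal, wavelengths, cfg, path) {
  members <- lapply(fusion$members$models, function(m) {
    list(x_mean = m$x_mean, y_mean = m$y_mean, B = m$B,
         n_lv = m$n_lv, column_index = m$column_index)
  })
  bundle <- list(
    wavelengths = wavelengths,
    pretreatment = tr_cal$method,
    msc_reference = tr_cal$msc_reference,
    n = fusion$n,
    beta0 = fusion$beta0,
    beta = fusion$beta,
    lambda = fusion$lambda,
    selected = fusion$selected,
    division = list(p = attr(fusion$members$division, "p"),
                    start = fusion$members$division$start,
                    end = fusion$members$division$end),
    members = members,
    config = cfg
  )
  # I(17) = 17 significant digits, enough to round-trip doubles bitwise
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

read_bundle <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Predict from a stored model bundle
#'
#' Reloads the pretreatment state and fusion model written by [run_fit()]
#' and applies them to new spectra. Refuses spectra whose wavelength axis
#' does not match the stored one.
#'
#' @param bundle_path Path to `bundle.json`.
#' @param spectra_path Spectra CSV in the package dialect.
#' @param out_path Optional path for a predictions CSV (`id,predicted_HU`).
#' @return A tibble with columns `id` and `predicted_HU` (zero rows for an
#'   empty input).
#' @export
run_predict <- function(bundle_path, spectra_path, out_path = NULL) {
  b <- read_bundle(bundle_path)
  ds <- read_spectra(spectra_path)
  if (length(ds$wavelengths) != length(b$wavelengths) ||
      max(abs(ds$wavelengths - b$wavelengths)) > 1e-8) {
    abort("wavelength axis does not match the stored model",
          class = "iplslasso_axis_error")
  }
  X <- switch(b$pretreatment,
    none = ds$X,
    snv = snv(ds$X),
    msc = msc(ds$X, reference = b$msc_reference)$X,
    d1st_sg = sg_first_derivative(ds$X)
  )
  Zp <- vapply(seq_len(b$n), function(j) {
    m <- b$members[[j]]
    cols <- as.integer(m$column_index)
    # same centering-then-product order as predict.pls_model, so reloaded
    # predictions are bit-identical to the in-memory model's
    as.vector(sweep(X[, cols, drop = FALSE], 2, m$x_mean) %*% m$B) + m$y_mean
  }, numeric(nrow(X)))
  Zp <- matrix(Zp, nrow = nrow(X))
  pred <- if (b$n == 1) Zp[, 1] else as.vector(Zp %*% b$beta) + b$beta0
  out <- tibble(id = ds$sample_ids, predicted_HU = pred)
  if (!is.null(out_path)) readr::write_csv(out, out_path)
  out
}
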