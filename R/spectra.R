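#' Spectral dataset container
#'
#' A `spectra_set` bundles a wavelength axis, a samples-by-wavelengths matrix
#' of semi-transmittance values (%T), an optional reference vector (Haugh
#' units) and a per-sample metadata tibble. It is the object every modeling
#' stage consumes; accessors and tidiers return tibbles.
#'
#' @param wavelengths Strictly increasing numeric vector (nm).
#' @param X Numeric matrix, samples in rows, one column per wavelength.
#' @param y Optional numeric reference vector (HU), one value per sample.
#' @param sample_ids Character labels, one per sample. Defaults to `s1..sn`.
#' @param meta Optional data frame of per-sample metadata (storage day,
#'   weight, replicate index, ...). Coerced to a tibble.
#' @return A validated object of class `spectra_set`.
#' @examples
#' ds <- spectra_set(c(550, 551, 552), matrix(rnorm(6), 2), y = c(80, 75))
#' n_samples(ds)
#' @export
spectra_set <- function(wavelengths, X, y = NULL, sample_ids = NULL, meta = NULL) {
  X <- check_numeric_matrix(X)
  wavelengths <- as.numeric(wavelengths)
  if (anyNA(wavelengths) || any(diff(wavelengths) <= 0)) {
    abort("`wavelengths` must be strictly increasing and finite",
          class = "iplslasso_axis_error")
  }
  if (length(wavelengths) != ncol(X)) {
    abort(sprintf("X has %d columns but %d wavelengths supplied",
                  ncol(X), length(wavelengths)),
          class = "iplslasso_shape_error")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(X)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(X) || anyDuplicated(sample_ids)) {
    abort("`sample_ids` must be unique, one per row of X",
          class = "iplslasso_input_error")
  }
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != nrow(X) || !all(is.finite(y))) {
      abort("`y` must be finite with one value per sample",
            class = "iplslasso_input_error")
    }
  }
  if (!is.null(meta)) {
    meta <- as_tibble(meta)
    if (nrow(meta) != nrow(X)) {
      abort("`meta` must have one row per sample", class = "iplslasso_input_error")
    }
  }
  dimnames(X) <- NULL
  structure(
    list(wavelengths = wavelengths, X = X, y = y,
         sample_ids = sample_ids, meta = meta),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavelengths (%.1f-%.1f nm)%s\n",
              nrow(x$X), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              if (is.null(x$y)) "" else ", with reference values"))
  if (!is.null(x$meta)) {
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname spectra_set
#' @param ds A `spectra_set`.
#' @export
n_samples <- function(ds) nrow(ds$X)

#' @rdname spectra_set
#' @export
n_wavelengths <- function(ds) length(ds$wavelengths)

#' Tidy a spectral dataset into long format
#'
#' @param x A `spectra_set`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `wavelength`, `transmittance`
#'   and, when present, `hu`.
#' @export
tidy.spectra_set <- function(x, ...) {
  out <- tibble(
    sample_id = rep(x$sample_ids, each = length(x$wavelengths)),
    wavelength = rep(x$wavelengths, times = nrow(x$X)),
    transmittance = as.vector(t(x$X))
  )
  if (!is.null(x$y)) out$hu <- rep(x$y, each = length(x$wavelengths))
  out
}

subset_samples <- function(ds, idx) {
  spectra_set(ds$wavelengths, ds$X[idx, , drop = FALSE],
              y = if (is.null(ds$y)) NULL else ds$y[idx],
              sample_ids = ds$sample_ids[idx],
              meta = if (is.null(ds$meta)) NULL else ds$meta[idx, , drop = FALSE])
}

#' Read a spectral dataset from CSV
#'
#' The matrix dialect is: header row `id` followed by wavelengths in nm; each
#' subsequent row a sample id followed by %T values. Reference values come
#' from a companion CSV keyed by id with columns `id,HU` and optional
#' metadata columns (`weight_g`, `day`, `replicate`, ...).
#'
#' @param path Path to the spectra CSV.
#' @param reference_path Optional path to the reference CSV.
#' @return A `spectra_set`.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, reference_path = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "iplslasso_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) {
    abort("spectra CSV needs a wavelength header row",
          class = "iplslasso_format_error")
  }
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  wl <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(wl)) {
    abort("non-numeric wavelength in header row", class = "iplslasso_format_error")
  }
  if (any(diff(wl) <= 0)) {
    abort("wavelength header is not strictly increasing",
          class = "iplslasso_axis_error")
  }
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  nc <- lengths(rows)
  if (any(nc != length(header))) {
    bad <- which(nc != length(header))[1]
    abort(sprintf("ragged row %d: %d fields, expected %d",
                  bad + 1L, nc[bad], length(header)),
          class = "iplslasso_format_error")
  }
  ids <- vapply(rows, `[[`, character(1), 1L)
  X <- matrix(NA_real_, length(rows), length(wl))
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[i]][-1]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      abort(sprintf("non-numeric value at row %d, column %d (sample %s)",
                    i + 1L, j + 1L, ids[i]),
            class = "iplslasso_parse_error")
    }
    X[i, ] <- vals
  }
  y <- NULL
  meta <- NULL
  if (!is.null(reference_path)) {
    ref <- readr::read_csv(reference_path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("id", "HU") %in% names(ref))) {
      abort("reference CSV must have columns `id` and `HU`",
            class = "iplslasso_format_error")
    }
    pos <- match(ids, as.character(ref$id))
    if (anyNA(pos)) {
      abort(sprintf("no reference row for sample(s): %s",
                    paste(ids[is.na(pos)], collapse = ", ")),
            class = "iplslasso_join_error")
    }
    ref <- ref[pos, , drop = FALSE]
    y <- ref$HU
    extra <- setdiff(names(ref), c("id", "HU"))
    if (length(extra)) meta <- ref[, extra, drop = FALSE]
  }
  spectra_set(wl, X, y = y, sample_ids = ids, meta = meta)
}

#' Write a spectral dataset to CSV
#'
#' Values are written with 17 significant digits so a read/write round trip
#' reproduces the matrix bitwise.
#'
#' @param ds A `spectra_set`.
#' @param path Output path for the spectra CSV.
#' @param reference_path Optional output path for the companion reference CSV
#'   (written only if `ds` carries reference values).
#' @return `ds`, invisibly.
#' @export
write_spectra <- function(ds, path, reference_path = NULL) {
  stopifnot(inherits(ds, "spectra_set"))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  header <- paste(c("id", fmt(ds$wavelengths)), collapse = ",")
  body <- vapply(seq_len(nrow(ds$X)), function(i) {
    paste(c(ds$sample_ids[i], fmt(ds$X[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  if (!is.null(reference_path) && !is.null(ds$y)) {
    ref <- tibble(id = ds$sample_ids, HU = ds$y)
    if (!is.null(ds$meta)) ref <- dplyr::bind_cols(ref, ds$meta)
    readr::write_csv(ref, reference_path)
  }
  invisible(ds)
}

#' Crop the wavelength axis
#'
#' Removes columns outside `[lo, hi]`, preserving order — the usual trim of
#' noisy detector edges before modeling.
#'
#' @param ds A `spectra_set`.
#' @param lo,hi Bounds in nm, `lo < hi`.
#' @return The cropped `spectra_set`.
#' @export
crop_wavelengths <- function(ds, lo, hi) {
  stopifnot(inherits(ds, "spectra_set"))
  if (!(lo < hi)) {
    abort("`lo` must be smaller than `hi`", class = "iplslasso_range_error")
  }
  keep <- ds$wavelengths >= lo & ds$wavelengths <= hi
  if (!any(keep)) {
    abort(sprintf("no wavelengths inside [%g, %g]", lo, hi),
          class = "iplslasso_range_error")
  }
  spectra_set(ds$wavelengths[keep], ds$X[, keep, drop = FALSE],
              y = ds$y, sample_ids = ds$sample_ids, meta = ds$meta)
}

#' Average replicate spectra per group
#'
#' Computes the arithmetic mean spectrum over the members of each group
#' (typically the three rotational readings of one egg). Reference values
#' must be constant within a group and are carried through.
#'
#' @param ds A `spectra_set` whose `meta` contains `group_key`.
#' @param group_key Name of the metadata column identifying the group.
#' @return A `spectra_set` with one row per group, ordered by first
#'   appearance; group labels become the sample ids and per-group constant
#'   metadata columns are retained.
#' @export
average_replicates <- function(ds, group_key) {
  stopifnot(inherits(ds, "spectra_set"))
  if (is.null(ds$meta) || !group_key %in% names(ds$meta)) {
    abort(sprintf("metadata column `%s` not found", group_key),
          class = "iplslasso_input_error")
  }
  g <- as.character(ds$meta[[group_key]])
  groups <- unique(g)
  gi <- match(g, groups)
  Xm <- rowsum(ds$X, gi, reorder = TRUE) / as.vector(table(gi))
  y <- NULL
  if (!is.null(ds$y)) {
    spread <- tapply(ds$y, gi, function(v) diff(range(v)))
    if (any(spread > 0)) {
      abort(sprintf("reference values differ within group(s): %s",
                    paste(groups[as.integer(names(spread)[spread > 0])],
                          collapse = ", ")),
            class = "iplslasso_consistency_error")
    }
    y <- as.numeric(tapply(ds$y, gi, `[`, 1))
  }
  meta <- NULL
  keep_cols <- setdiff(names(ds$meta), group_key)
  if (length(keep_cols)) {
    first_rows <- match(seq_along(groups), gi)
    constant <- vapply(keep_cols, function(cl) {
      all(tapply(as.character(ds$meta[[cl]]), gi,
                 function(v) length(unique(v)) == 1))
    }, logical(1))
    if (any(constant)) {
      meta <- ds$meta[first_rows, keep_cols[constant], drop = FALSE]
    }
  }
  spectra_set(ds$wavelengths, Xm, y = y, sample_ids = groups, meta = meta)
}

#' Flag outlying samples
#'
#' Spectral outliers are flagged by the Mahalanobis distance of PCA scores
#' (components retaining at least `var_explained` of the variance) against a
#' chi-square cutoff at `1 - alpha`; reference outliers by a two-sided z-score
#' test on the reference values at the same significance level. The routine is
#' deterministic given the dataset.
#'
#' @param ds A `spectra_set` with at least 10 samples.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param var_explained Fraction of spectral variance the retained principal
#'   components must reach (default 0.99).
#' @return A tibble with columns `sample_id`, `type` (`"spectral"` or
#'   `"reference"`) and `statistic` (squared Mahalanobis distance or |z|),
#'   one row per flag; zero rows when nothing is flagged.
#' @export
detect_outliers <- function(ds, alpha = 0.05, var_explained = 0.99) {
  stopifnot(inherits(ds, "spectra_set"))
  n <- n_samples(ds)
  if (n < 10) {
    abort("outlier detection needs at least 10 samples",
          class = "iplslasso_input_error")
  }
  if (!(alpha > 0 && alpha < 1)) {
    abort("`alpha` must lie in (0, 1)", class = "iplslasso_input_error")
  }
  pc <- prcomp(ds$X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  pos <- ev > 1e-12 * sum(ev)
  cum <- cumsum(ev) / sum(ev)
  ncomp <- max(1L, min(which(cum >= var_explained)))
  ncomp <- min(ncomp, sum(pos))
  if (ncomp >= n) {
    abort("fewer samples than retained components",
          class = "iplslasso_df_error")
  }
  d2 <- rowSums(sweep(pc$x[, seq_len(ncomp), drop = FALSE]^2, 2,
                      ev[seq_len(ncomp)], `/`))
  cut_spec <- qchisq(1 - alpha, df = ncomp)
  spec_idx <- which(d2 > cut_spec)

  ref_idx <- integer(0)
  z <- numeric(0)
  if (!is.null(ds$y) && sd(ds$y) > 0) {
    z <- abs(ds$y - mean(ds$y)) / sd(ds$y)
    ref_idx <- which(z > qnorm(1 - alpha / 2))
  }
  dplyr::bind_rows(
    tibble(sample_id = ds$sample_ids[spec_idx], type = "spectral",
           statistic = unname(d2[spec_idx])),
    tibble(sample_id = ds$sample_ids[ref_idx], type = "reference",
           statistic = unname(z[ref_idx]))
  )
}

#' Remove flagged samples
#'
#' @param ds A `spectra_set`.
#' @param flags Result of [detect_outliers()] or a character vector of ids.
#' @return `ds` without the flagged samples.
#' @export
remove_outliers <- function(ds, flags) {
  ids <- if (is.data.frame(flags)) unique(flags$sample_id) else as.character(flags)
  keep <- !(ds$sample_ids %in% ids)
  if (!any(keep)) abort("removal would leave no samples",
                        class = "iplslasso_input_error")
  subset_samples(ds, which(keep))
}

#' Split into calibration and prediction sets
#'
#' Samples are assigned by a seeded uniform shuffle. The calibration size is
#' `round_half_up(n * cal / (cal + pred))`, so 103 samples at 2:1 give 69
#' calibration and 34 prediction rows.
#'
#' @param ds A `spectra_set` (outliers already removed).
#' @param ratio Length-2 numeric `c(cal, pred)`, default `c(2, 1)`.
#' @param seed Integer seed; the split is reproducible for a fixed seed.
#' @return A list of class `split_result` with elements `calibration` and
#'   `prediction` (both `spectra_set`) and the integer `seed`.
#' @export
split_calibration <- function(ds, ratio = c(2, 1), seed = 1) {
  stopifnot(inherits(ds, "spectra_set"))
  if (length(ratio) != 2 || any(ratio <= 0)) {
    abort("`ratio` must be two positive numbers c(cal, pred)",
          class = "iplslasso_input_error")
  }
  n <- n_samples(ds)
  n_cal <- round_half_up(n * ratio[1] / sum(ratio))
  if (n_cal < 1 || n_cal >= n) {
    abort("split would leave an empty subset", class = "iplslasso_size_error")
  }
  perm <- with_local_seed(seed, sample.int(n))
  cal_idx <- sort(perm[seq_len(n_cal)])
  pred_idx <- sort(perm[-seq_len(n_cal)])
  structure(
    list(calibration = subset_samples(ds, cal_idx),
         prediction = subset_samples(ds, pred_idx),
         seed = seed),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> calibration: %d, prediction: %d (seed %d)\n",
              n_samples(x$calibration), n_samples(x$prediction), x$seed))
  invisible(x)
}
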