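test_that("read/write round trip preserves values bitwise", {
  ds <- tiny_spectra(n = 3, p = 4, seed = 11,
                     meta = tibble::tibble(day = c(1, 1, 3)))
  sp_path <- withr::local_tempfile(fileext = ".csv")
  ref_path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, sp_path, reference_path = ref_path)
  back <- read_spectra(sp_path, ref_path)
  expect_identical(back$X, ds$X)
  expect_identical(back$wavelengths, ds$wavelengths)
  expect_identical(back$y, ds$y)
  expect_identical(back$sample_ids, ds$sample_ids)
  expect_equal(back$meta$day, ds$meta$day)
})

test_that("malformed spectra files raise named errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,554,553,552", "a,1,2,3"), path)
  expect_error(read_spectra(path), class = "iplslasso_axis_error")

  writeLines(c("id,550,551,552", "a,1,2"), path)
  expect_error(read_spectra(path), "ragged",
               class = "iplslasso_format_error")

  writeLines(c("id,550,551,552", "a,1,oops,3"), path)
  expect_error(read_spectra(path), "row 2, column 3",
               class = "iplslasso_parse_error")

  writeLines(c("id,550,551,552", "a,1,2,3", "b,4,5,6"), path)
  ref <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,HU", "a,80"), ref)
  expect_error(read_spectra(path, ref), class = "iplslasso_join_error")
})

test_that("crop keeps the requested window and composes", {
  ds <- tiny_spectra(n = 5, p = 40, seed = 2)
  expect_identical(crop_wavelengths(ds, min(ds$wavelengths),
                                    max(ds$wavelengths))$X, ds$X)

  small <- spectra_set(c(1, 2, 3, 4), matrix(1:8, 2))
  expect_equal(n_wavelengths(crop_wavelengths(small, 2, 3)), 2)
  expect_error(crop_wavelengths(small, 10, 20), class = "iplslasso_range_error")
  expect_error(crop_wavelengths(small, 3, 2), class = "iplslasso_range_error")

  # nested crops equal the single inner crop
  outer <- crop_wavelengths(ds, 555, 585)
  expect_identical(crop_wavelengths(outer, 560, 575)$X,
                   crop_wavelengths(ds, 560, 575)$X)
})

test_that("replicate averaging is a grouped arithmetic mean", {
  X <- rbind(c(0, 2), c(2, 0), c(5, 5))
  ds <- spectra_set(c(1, 2), X, y = c(7, 7, 3),
                    sample_ids = c("a1", "a2", "b1"),
                    meta = tibble::tibble(egg = c("a", "a", "b")))
  avg <- average_replicates(ds, "egg")
  expect_equal(n_samples(avg), 2)
  expect_equal(avg$X[1, ], c(1, 1))
  expect_equal(avg$y, c(7, 3))
  expect_equal(avg$sample_ids, c("a", "b"))

  # idempotence on identical rows
  ds3 <- spectra_set(c(1, 2), matrix(rep(c(4, 9), each = 3), 3), y = rep(1, 3),
                     meta = tibble::tibble(egg = rep("a", 3)))
  expect_equal(average_replicates(ds3, "egg")$X[1, ], c(4, 9))

  # conflicting reference values within a group
  bad <- spectra_set(c(1, 2), X, y = c(7, 8, 3),
                     meta = tibble::tibble(egg = c("a", "a", "b")))
  expect_error(average_replicates(bad, "egg"),
               class = "iplslasso_consistency_error")
})

test_that("outlier detection flags gross and planted anomalies", {
  base <- matrix(rnorm(20 * 15, sd = 1), 20, 15)
  X <- sweep(base, 2, seq_len(15) * 0, `+`)
  X[7, ] <- X[7, ] + 100
  ds <- spectra_set(seq_len(15), X, y = rep(1, 20) + rnorm(20, sd = 0.01))
  flags <- detect_outliers(ds)
  expect_true("s7" %in% flags$sample_id[flags$type == "spectral"])

  # constant y produces no reference flags
  ds0 <- spectra_set(seq_len(15), base, y = rep(5, 20))
  expect_false("reference" %in% detect_outliers(ds0)$type)

  # planted 105-sample outliers at 10x noise: both flagged and top-2 by
  # distance (independent ranking oracle)
  sim <- iplslasso:::with_local_seed(5, {
    S <- matrix(rnorm(105 * 50, sd = 0.2), 105, 50)
    S[c(13, 77), ] <- S[c(13, 77), ] + rnorm(2 * 50, sd = 2)
    S
  })
  ds2 <- spectra_set(seq_len(50), sim)
  fl2 <- detect_outliers(ds2)
  spec_ids <- fl2$sample_id[fl2$type == "spectral"]
  expect_true(all(c("s13", "s77") %in% spec_ids))
  d_centered <- scale(sim, scale = FALSE)
  dist_rank <- order(rowSums(d_centered^2), decreasing = TRUE)
  expect_setequal(dist_rank[1:2], c(13, 77))
})

test_that("outlier detection is permutation-equivariant", {
  ds <- tiny_spectra(n = 30, p = 20, seed = 9)
  ds$X[4, ] <- ds$X[4, ] * 8
  perm <- iplslasso:::with_local_seed(3, sample.int(30))
  ds_perm <- spectra_set(ds$wavelengths, ds$X[perm, ], y = ds$y[perm],
                         sample_ids = ds$sample_ids[perm])
  f1 <- detect_outliers(ds)
  f2 <- detect_outliers(ds_perm)
  expect_setequal(f1$sample_id, f2$sample_id)
})

test_that("calibration split follows the round-half-up 2:1 rule", {
  ds103 <- tiny_spectra(n = 103, p = 5, seed = 4)
  sp <- split_calibration(ds103, ratio = c(2, 1), seed = 1)
  expect_equal(n_samples(sp$calibration), 69)
  expect_equal(n_samples(sp$prediction), 34)

  ds3 <- tiny_spectra(n = 3, p = 5, seed = 4)
  sp3 <- split_calibration(ds3, seed = 1)
  expect_equal(n_samples(sp3$calibration), 2)

  # determinism
  sp_b <- split_calibration(ds103, ratio = c(2, 1), seed = 1)
  expect_identical(sp$calibration$sample_ids, sp_b$calibration$sample_ids)
})

test_that("split is a partition with the documented sizes for n in 3..200", {
  for (n in 3:200) {
    ids <- paste0("x", seq_len(n))
    ds <- spectra_set(c(1, 2), matrix(rnorm(2 * n), n), sample_ids = ids)
    sp <- split_calibration(ds, ratio = c(2, 1), seed = n)
    expect_equal(n_samples(sp$calibration), floor(n * 2 / 3 + 0.5))
    expect_setequal(c(sp$calibration$sample_ids, sp$prediction$sample_ids), ids)
    expect_length(intersect(sp$calibration$sample_ids,
                            sp$prediction$sample_ids), 0)
  }
})
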