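# NIfTI ingestion, mask binarization, slice extraction and the PNG dataset.

write_pair <- function(dir, scan, mask) {
  fs <- file.path(dir, "scan.nii.gz"); fm <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(scan), fs)
  RNifti::writeNifti(RNifti::asNifti(mask), fm)
  list(scan = fs, mask = fm)
}

test_that("a phantom-generated NIfTI pair round-trips with identical voxels", {
  dir <- withr::local_tempdir()
  cs <- cohort_spec(n_patients = 2, ich_fraction = 0.5, slices_per_scan = 4, rng_seed = 5)
  mf <- generate_cohort(cs, tiny_phantom(32), dir)
  pid <- unique(mf$patient_id)[1]
  rows <- mf[mf$patient_id == pid, ]
  pair <- read_nifti_pair(file.path(dir, rows$file_scan[1]),
                          file.path(dir, rows$file_mask[1]), patient_id = pid)
  expect_s3_class(pair, "ct_volume_pair")
  expect_identical(dim(pair$scan), dim(pair$mask))
  # writing the read-back volume again reproduces the same voxel values
  dir2 <- withr::local_tempdir()
  p2 <- write_pair(dir2, pair$scan, pair$mask)
  pair2 <- read_nifti_pair(p2$scan, p2$mask)
  expect_equal(pair2$scan, pair$scan)
  expect_equal(pair2$mask, pair$mask)
})

test_that("invalid volumes are rejected with informative data errors", {
  dir <- withr::local_tempdir()
  scan <- array(runif(4 * 4 * 3), c(4, 4, 3))
  bad_mask <- array(0, c(4, 4, 3)); bad_mask[1, 1, 1] <- 17
  p <- write_pair(dir, scan, bad_mask)
  expect_error(read_nifti_pair(p$scan, p$mask), "17", class = "hemoseg_data_error")

  dir2 <- withr::local_tempdir()
  fs <- file.path(dir2, "s.nii.gz"); fm <- file.path(dir2, "m.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 3))), fs)
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 2))), fm)
  expect_error(read_nifti_pair(fs, fm), "4x4x3", class = "hemoseg_data_error")
  expect_error(read_nifti_pair(file.path(dir2, "absent.nii.gz"), fm),
               "absent", class = "hemoseg_file_error")
})

test_that("mask binarization maps 255 to 1, is idempotent, and rejects junk", {
  z <- matrix(0, 5, 5)
  expect_equal(binarize_mask(z), z)
  m <- matrix(0, 6, 6); m[2:3, 4] <- 255
  b <- binarize_mask(m)
  expect_equal(sum(b), 2)
  expect_true(all(b %in% c(0, 1)))
  expect_identical(binarize_mask(b), b)
  bad <- m; bad[1, 1] <- 3
  expect_error(binarize_mask(bad), "3", class = "hemoseg_data_error")
})

test_that("slice normalization is monotone with min 0 and max 1; constant slices map to zero", {
  set.seed(2)
  x <- matrix(runif(64, 5, 9), 8, 8)
  n <- normalize_slice(x)
  expect_equal(min(n), 0)
  expect_equal(max(n), 1)
  expect_equal(order(as.vector(n)), order(as.vector(x)))
  expect_equal(normalize_slice(matrix(7, 4, 4)), matrix(0, 4, 4))
})

test_that("hemorrhage slice extraction returns exactly the positive slices in order", {
  side <- 24L
  nz <- 9L
  scan <- array(runif(side * side * nz), c(side, side, nz))
  mask <- array(0, c(side, side, nz))
  mask[10:12, 10:12, 4] <- 255   # 0-based slice index 3
  mask[5:6, 5:6, 8] <- 255       # 0-based slice index 7
  pair <- structure(list(scan = scan, mask = mask, patient_id = "T1",
                         age = 30, sex = "female", spacing = c(1, 1, 5)),
                    class = "ct_volume_pair")
  lookup <- c("3" = "subdural", "7" = "epidural")
  out <- extract_hemorrhage_slices(pair, lookup)
  expect_length(out, 2L)
  expect_equal(vapply(out, function(s) s$slice_index, 0L), c(3L, 7L))
  expect_equal(vapply(out, function(s) s$subtype, ""), c("subdural", "epidural"))
  expect_true(all(vapply(out, function(s) all(s$image >= 0 & s$image <= 1), TRUE)))
  # brute-force oracle: count of z-indices with nonzero mask sum
  expect_length(out, sum(apply(mask, 3, sum) > 0))

  # empty-mask volume gives an empty list
  pair0 <- pair; pair0$mask[] <- 0
  expect_length(extract_hemorrhage_slices(pair0, lookup), 0L)

  # positive slice without a subtype is an error
  expect_error(extract_hemorrhage_slices(pair, c("3" = "subdural")),
               "subtype", class = "hemoseg_data_error")
})

test_that("extraction count matches the brute-force oracle on random phantom volumes", {
  ps <- tiny_phantom(24)
  for (seed in 1:3) {
    withr::with_seed(seed, {
      nz <- 8L
      subtypes <- ifelse(runif(nz) < 0.4,
                         sample(ich_subtypes(), nz, replace = TRUE), "none")
      scan <- array(0, c(24, 24, nz)); mask <- array(0, c(24, 24, nz))
      for (z in seq_len(nz)) {
        s <- generate_phantom_slice(ps, subtypes[z], seed = 50 * seed + z)
        scan[, , z] <- s$image; mask[, , z] <- s$mask * 255
      }
    })
    pair <- structure(list(scan = scan, mask = mask, patient_id = "T",
                           age = 40, sex = "male", spacing = c(1, 1, 5)),
                      class = "ct_volume_pair")
    lookup <- setNames(subtypes, as.character(seq_len(nz) - 1L))
    out <- extract_hemorrhage_slices(pair, lookup)
    expect_length(out, sum(apply(mask, 3, sum) > 0))
  }
})

test_that("the PNG slice dataset round-trips masks exactly and images to 8-bit precision", {
  dir <- withr::local_tempdir()
  samples <- phantom_batch(4, side = 32)
  mf <- write_slice_dataset(samples, dir)
  expect_equal(nrow(mf), 4L)
  back <- read_slice_dataset(dir)
  expect_length(back, 4L)
  for (i in 1:4) {
    expect_identical(back[[i]]$mask, samples[[i]]$mask)
    expect_lt(max(abs(back[[i]]$image - samples[[i]]$image)), 1 / 255)
    expect_equal(back[[i]]$subtype, samples[[i]]$subtype)
  }
})

test_that("prepare_slices pulls all hemorrhage slices of a cohort with metadata", {
  dir <- withr::local_tempdir()
  cs <- cohort_spec(n_patients = 4, ich_fraction = 0.5, slices_per_scan = 5, rng_seed = 9)
  mf <- generate_cohort(cs, tiny_phantom(32), dir)
  samples <- prepare_slices(file.path(dir, "manifest.csv"), dir)
  expect_length(samples, sum(mf$subtype != "none"))
  expect_true(all(vapply(samples, function(s) s$subtype %in% ich_subtypes(), TRUE)))
  expect_true(all(vapply(samples, function(s) is.finite(s$age), TRUE)))
})
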