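# NIfTI ingestion and slice-level dataset preparation: read scan/mask volume
# pairs, binarize masks (255 -> 1), extract the hemorrhage-bearing slices and
# min-max normalize them, and read/write the PNG + CSV slice dataset layout.

#' One CT slice with its annotation
#'
#' The atomic training unit: a 2-D grayscale image in `[0, 1]`, a binary
#' mask of the same shape, the hemorrhage subtype, patient metadata, and a
#' provenance tag recording which augmentation (if any) produced it.
#'
#' @param image 2-D numeric matrix with values in `[0, 1]`.
#' @param mask 2-D matrix of 0/1 values, same shape as `image`.
#' @param subtype One of [ich_subtypes()], `"none"`, or `"ICH"` (the merged
#'   class used after augmentation).
#' @param patient_id Patient identifier.
#' @param slice_index 0-based index of the slice within its scan.
#' @param provenance One of `"original"`, `"hflip"`, `"vflip"`,
#'   `"bright_up"`, `"bright_down"`, `"rot_p10"`, `"rot_m5"`.
#' @param age,sex Optional patient metadata.
#' @return An object of class `slice_sample`.
#' @export
slice_sample <- function(image, mask, subtype = "none", patient_id = NA_character_,
                         slice_index = 0L, provenance = "original",
                         age = NA_real_, sex = NA_character_) {
  if (!identical(dim(image), dim(mask)))
    hs_data_error(sprintf("image is %s but mask is %s",
                          paste(dim(image), collapse = "x"),
                          paste(dim(mask), collapse = "x")))
  bad <- setdiff(unique(as.vector(mask)), c(0, 1))
  if (length(bad) > 0)
    hs_data_error(sprintf("mask contains values other than 0/1: %s",
                          paste(head(bad, 5), collapse = ", ")))
  structure(list(image = image, mask = mask, subtype = subtype,
                 patient_id = patient_id, slice_index = as.integer(slice_index),
                 provenance = provenance, age = age, sex = sex),
            class = "slice_sample")
}

#' @export
print.slice_sample <- function(x, ...) {
  cat(sprintf("<slice_sample> %dx%d, subtype=%s, patient=%s, z=%d, provenance=%s, mask px=%d\n",
              nrow(x$image), ncol(x$image), x$subtype, x$patient_id,
              x$slice_index, x$provenance, sum(x$mask)))
  invisible(x)
}

#' Read a CT scan / mask NIfTI pair
#'
#' Both volumes must exist, parse as NIfTI, and have identical shapes; the
#' mask may only contain the values `{0, 255}` (raw annotation convention)
#' or `{0, 1}` (already binarized).
#'
#' @param scan_path,mask_path Paths to the NIfTI files.
#' @param patient_id,age,sex Metadata attached to the pair.
#' @return A list of class `ct_volume_pair` with elements `scan`, `mask`,
#'   `patient_id`, `age`, `sex`, and `spacing` (voxel spacing in mm).
#' @export
read_nifti_pair <- function(scan_path, mask_path, patient_id = NA_character_,
                            age = NA_real_, sex = NA_character_) {
  read1 <- function(p) {
    if (!file.exists(p)) hs_file_error(sprintf("NIfTI file not found: '%s'", p))
    img <- tryCatch(RNifti::readNifti(p),
                    error = function(e) hs_file_error(
                      sprintf("cannot read NIfTI file '%s': %s", p, conditionMessage(e))))
    img
  }
  scan <- read1(scan_path)
  mask <- read1(mask_path)
  if (!identical(dim(scan), dim(mask)))
    hs_data_error(sprintf("scan shape %s does not match mask shape %s",
                          paste(dim(scan), collapse = "x"),
                          paste(dim(mask), collapse = "x")))
  vals <- unique(as.vector(mask))
  if (!(all(vals %in% c(0, 255)) || all(vals %in% c(0, 1))))
    hs_data_error(sprintf("mask contains values outside {0, 255}/{0, 1}: %s",
                          paste(head(setdiff(vals, c(0, 1, 255)), 5), collapse = ", ")))
  spacing <- tryCatch(RNifti::pixdim(scan), error = function(e) rep(NA_real_, 3))
  strip <- function(x) {
    a <- as.array(x)
    attributes(a) <- list(dim = dim(a))
    a
  }
  structure(list(scan = strip(scan), mask = strip(mask),
                 patient_id = patient_id, age = age, sex = sex,
                 spacing = spacing),
            class = "ct_volume_pair")
}

#' Binarize an annotation mask
#'
#' Maps the raw annotation convention (background 0, hemorrhage 255) to the
#' training convention (0/1). Already-binary input passes through unchanged,
#' so the operation is idempotent.
#'
#' @param mask_slice Numeric matrix or array with values in `{0, 255}` or
#'   `{0, 1}`.
#' @return Same shape, values in `{0, 1}`.
#' @export
binarize_mask <- function(mask_slice) {
  vals <- unique(as.vector(mask_slice))
  if (!(all(vals %in% c(0, 255)) || all(vals %in% c(0, 1))))
    hs_data_error(sprintf("mask contains values outside {0, 255}/{0, 1}: %s",
                          paste(head(setdiff(vals, c(0, 1, 255)), 5), collapse = ", ")))
  out <- (mask_slice != 0) * 1
  if (!is.null(dim(mask_slice))) dim(out) <- dim(mask_slice)
  out
}

#' Min-max normalize a slice to `[0, 1]`
#'
#' Monotone per-slice rescaling mapping the minimum to 0 and the maximum
#' to 1. A constant slice (max == min) carries no signal and maps to all
#' zeros rather than dividing by zero.
#'
#' @param img 2-D numeric matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_slice <- function(img) {
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(img * 0)
  (img - lo) / (hi - lo)
}

#' Extract hemorrhage-bearing slices from a volume pair
#'
#' Returns exactly the slices (third NIfTI axis, 0-based index) whose
#' binarized mask has at least one positive pixel, in ascending slice
#' order, with the subtype attached from `subtype_lookup` and images
#' min-max normalized per slice.
#'
#' @param pair A `ct_volume_pair` from [read_nifti_pair()].
#' @param subtype_lookup Named character vector or function mapping a
#'   0-based slice index to a subtype; alternatively a data frame with
#'   columns `slice_index` and `subtype`.
#' @param hu_window Optional `c(center, width)` Hounsfield window applied
#'   (clamp to `center +/- width/2`) before normalization, for raw HU
#'   volumes; `NULL` (the default) assumes pre-windowed grayscale input.
#' @return List of [slice_sample()] objects.
#' @export
extract_hemorrhage_slices <- function(pair, subtype_lookup, hu_window = NULL) {
  if (!inherits(pair, "ct_volume_pair")) hs_data_error("pair must be a ct_volume_pair")
  lookup <- subtype_lookup
  if (is.data.frame(lookup)) {
    lu <- setNames(as.character(lookup$subtype), as.character(lookup$slice_index))
    lookup <- function(z) if (as.character(z) %in% names(lu)) lu[[as.character(z)]] else NA_character_
  } else if (!is.function(lookup)) {
    lu <- lookup
    lookup <- function(z) if (as.character(z) %in% names(lu)) lu[[as.character(z)]] else NA_character_
  }
  nz <- dim(pair$mask)[3L]
  out <- list()
  for (z in seq_len(nz)) {
    mslice <- binarize_mask(pair$mask[, , z])
    if (sum(mslice) == 0) next
    subtype <- lookup(z - 1L)
    if (is.na(subtype) || !nzchar(subtype) || identical(subtype, "none"))
      hs_data_error(sprintf(
        "slice %d of patient %s has a positive mask but no subtype in the lookup",
        z - 1L, pair$patient_id))
    islice <- pair$scan[, , z]
    if (!is.null(hu_window)) {
      lo <- hu_window[1L] - hu_window[2L] / 2
      hi <- hu_window[1L] + hu_window[2L] / 2
      islice <- pmin(pmax(islice, lo), hi)
    }
    out[[length(out) + 1L]] <- slice_sample(
      normalize_slice(islice), mslice, subtype = subtype,
      patient_id = pair$patient_id, slice_index = z - 1L,
      age = pair$age, sex = pair$sex)
  }
  out
}

#' Prepare a training-ready slice dataset from a cohort directory
#'
#' Reads every scan/mask pair named in a cohort manifest, extracts the
#' hemorrhage-bearing slices, and returns them as a list of
#' [slice_sample()] objects.
#'
#' @param manifest Manifest data frame (as written by [generate_cohort()])
#'   or path to `manifest.csv`.
#' @param dir Directory holding the NIfTI files named in the manifest.
#' @param hu_window Optional `c(center, width)` Hounsfield window; see
#'   [extract_hemorrhage_slices()].
#' @return List of [slice_sample()] objects.
#' @export
prepare_slices <- function(manifest, dir, hu_window = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) hs_file_error(sprintf("manifest not found: '%s'", manifest))
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  out <- list()
  for (pid in unique(manifest$patient_id)) {
    rows <- manifest[manifest$patient_id == pid, ]
    pair <- read_nifti_pair(file.path(dir, rows$file_scan[1L]),
                            file.path(dir, rows$file_mask[1L]),
                            patient_id = pid, age = rows$age[1L], sex = rows$sex[1L])
    out <- c(out, extract_hemorrhage_slices(pair, rows[, c("slice_index", "subtype")],
                                            hu_window = hu_window))
  }
  out
}

#' Write a slice dataset as PNG pairs plus a CSV manifest
#'
#' Images are written as 8-bit grayscale PNGs; masks store `{0, 1}` as
#' `{0, 255}`.
#'
#' @param samples List of [slice_sample()] objects.
#' @param out_dir Output directory.
#' @return The manifest data frame.
#' @export
write_slice_dataset <- function(samples, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) hs_file_error(sprintf("cannot create directory '%s'", out_dir))
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    base <- sprintf("s%05d_%s_z%03d_%s", i, s$patient_id, s$slice_index, s$provenance)
    fi <- paste0(base, "_img.png"); fm <- paste0(base, "_mask.png")
    png::writePNG(pmin(pmax(s$image, 0), 1), file.path(out_dir, fi))
    png::writePNG(s$mask, file.path(out_dir, fm))
    data.frame(sample_id = base, file_image = fi, file_mask = fm,
               patient_id = s$patient_id, slice_index = s$slice_index,
               subtype = s$subtype, provenance = s$provenance,
               age = s$age, sex = s$sex, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "slices.csv"), row.names = FALSE)
  manifest
}

#' Read a slice dataset written by [write_slice_dataset()]
#'
#' @param dir Dataset directory containing `slices.csv`.
#' @return List of [slice_sample()] objects.
#' @export
read_slice_dataset <- function(dir) {
  mf <- file.path(dir, "slices.csv")
  if (!file.exists(mf)) hs_file_error(sprintf("slice manifest not found: '%s'", mf))
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    img <- png::readPNG(file.path(dir, r$file_image))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    msk <- png::readPNG(file.path(dir, r$file_mask))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
    slice_sample(img, (msk > 0.5) * 1, subtype = r$subtype,
                 patient_id = r$patient_id, slice_index = r$slice_index,
                 provenance = r$provenance, age = r$age, sex = r$sex)
  })
}
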