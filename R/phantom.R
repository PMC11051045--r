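# Phantom CT slices and cohorts. These emulate the statistical structure of
# a head-trauma CT dataset (a skull ring, noisy parenchyma, and hyperdense
# hemorrhage blobs whose morphology depends on the ICH subtype) so that the
# whole pipeline is exercisable without clinical data.

#' Phantom slice specification
#'
#' Geometry and intensity model for synthetic CT slices: a bright skull
#' annulus, noisy mid-gray parenchyma inside it, and per-subtype blob models
#' for the hemorrhage. All intensities are on a `[0, 1]` grayscale; radii
#' are fractions of the image side. Blob semi-axes are given in pixels at a
#' 512-pixel reference side and are scaled linearly with `side`.
#'
#' @param side Image side in pixels (square slices).
#' @param skull_inner,skull_outer Inner/outer skull radius as a fraction of
#'   the side; must satisfy `inner < outer < 0.5`.
#' @param skull_level Skull intensity.
#' @param parenchyma_level Brain tissue intensity.
#' @param noise_sd Standard deviation of the additive Gaussian noise applied
#'   inside the skull (clipped to `[0, 1]`).
#' @param blob_offset Intensity added to hemorrhage pixels (blood is
#'   hyperdense on CT).
#' @param blob_model Named list, one entry per subtype, each with `count`
#'   (min/max blobs), `semi_axes` (min/max semi-axis in reference pixels),
#'   and `region` (one of `"rim"`, `"parenchymal"`, `"central"`,
#'   `"diffuse"`). Defaults follow the visual morphology of the subtypes
#'   (rim crescents for epidural/subdural, central blobs for
#'   intraventricular, scattered small blobs for subarachnoid).
#' @param rng_seed Default seed used when none is passed to the generators.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(side = 512L,
                         skull_inner = 0.40, skull_outer = 0.47,
                         skull_level = 0.95,
                         parenchyma_level = 0.35, noise_sd = 0.04,
                         blob_offset = 0.30,
                         blob_model = default_blob_model(),
                         rng_seed = 1L) {
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      hs_config_error(sprintf("phantom_spec field '%s' must be a number in [0, 1]", nm))
  }
  chk01(skull_level, "skull_level")
  chk01(parenchyma_level, "parenchyma_level")
  chk01(blob_offset, "blob_offset")
  chk01(skull_inner, "skull_inner")
  chk01(skull_outer, "skull_outer")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    hs_config_error("phantom_spec field 'noise_sd' must be non-negative")
  if (!(skull_inner < skull_outer && skull_outer < 0.5))
    hs_config_error("phantom_spec radii must satisfy skull_inner < skull_outer < 0.5")
  if (side < 16L) hs_config_error("phantom_spec field 'side' must be at least 16")
  need <- ich_subtypes()
  if (!all(need %in% names(blob_model)))
    hs_config_error(sprintf("phantom_spec field 'blob_model' is missing subtypes: %s",
                            paste(setdiff(need, names(blob_model)), collapse = ", ")))
  structure(list(side = as.integer(side),
                 skull_inner = skull_inner, skull_outer = skull_outer,
                 skull_level = skull_level,
                 parenchyma_level = parenchyma_level, noise_sd = noise_sd,
                 blob_offset = blob_offset, blob_model = blob_model,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Default per-subtype blob models
#' @return Named list of blob model entries (see [phantom_spec()]).
#' @export
default_blob_model <- function() {
  list(
    epidural         = list(count = c(1L, 1L), semi_axes = c(55, 90),  aspect = c(0.40, 0.60), region = "rim"),
    subdural         = list(count = c(1L, 1L), semi_axes = c(75, 115), aspect = c(0.20, 0.32), region = "rim"),
    intraparenchymal = list(count = c(1L, 2L), semi_axes = c(32, 55),  aspect = c(0.60, 1.00), region = "parenchymal"),
    intraventricular = list(count = c(1L, 2L), semi_axes = c(26, 42),  aspect = c(0.55, 0.90), region = "central"),
    subarachnoid     = list(count = c(3L, 5L), semi_axes = c(20, 34),  aspect = c(0.50, 0.90), region = "diffuse")
  )
}

#' Rasterize a rotated ellipse
#'
#' Marks the pixels whose centers fall inside the ellipse with center
#' `(cx, cy)` (column, row; 1-based), semi-axes `a` and `b`, rotated by
#' `theta` radians.
#'
#' @param side Side of the square output matrix.
#' @param cx,cy Ellipse center (column, row).
#' @param a,b Semi-axes in pixels.
#' @param theta Rotation in radians.
#' @return Binary matrix.
#' @export
ellipse_mask <- function(side, cx, cy, a, b, theta = 0) {
  col <- matrix(rep(seq_len(side), each = side), side, side)
  row <- matrix(rep(seq_len(side), times = side), side, side)
  dx <- col - cx; dy <- row - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  ((u / a)^2 + (v / b)^2 <= 1) * 1
}

# Squared-distance-from-center matrix, reused by slice generation.
radius_grid <- function(side) {
  ctr <- (side + 1) / 2
  col <- matrix(rep(seq_len(side), each = side), side, side)
  row <- matrix(rep(seq_len(side), times = side), side, side)
  sqrt((col - ctr)^2 + (row - ctr)^2)
}

# Draw one blob mask for a subtype; guaranteed non-empty and strictly inside
# the inner skull radius.
draw_blob <- function(spec, model, r, ri, side) {
  scale <- side / 512
  ax <- runif(1, model$semi_axes[1L], model$semi_axes[2L]) * scale
  ax <- max(ax, 1.5)
  b <- max(ax * runif(1, model$aspect[1L], model$aspect[2L]), 1.0)
  ctr <- (side + 1) / 2
  phi <- runif(1, 0, 2 * pi)
  rad <- switch(model$region,
    rim = runif(1, 0.82, 0.94) * ri,
    parenchymal = runif(1, 0, 0.55) * ri,
    central = runif(1, 0, 0.25) * ri,
    diffuse = runif(1, 0, 0.78) * ri,
    hs_config_error(sprintf("unknown blob region '%s'", model$region)))
  cx <- ctr + rad * cos(phi)
  cy <- ctr + rad * sin(phi)
  # rim bleeds hug the skull: orient the long axis tangentially
  theta <- if (model$region == "rim") phi + pi / 2 else runif(1, 0, pi)
  m <- ellipse_mask(side, cx, cy, ax, b, theta)
  if (model$region == "rim") m <- m * (r >= 0.70 * ri)  # crescent: ellipse within annulus
  m <- m * (r < ri)                                     # strictly inside the skull
  if (sum(m) == 0) {                                    # degenerate draw: keep >= 1 pixel
    px <- round(min(max(cx, 1), side)); py <- round(min(max(cy, 1), side))
    if (r[py, px] < ri) m[py, px] <- 1
    else m[round(ctr), round(ctr)] <- 1
  }
  m
}

#' Generate one phantom CT slice
#'
#' Produces a square `[0, 1]` grayscale slice with a skull ring and noisy
#' parenchyma, plus a binary hemorrhage mask. With `subtype = "none"` the
#' mask is empty; otherwise blobs are placed according to the subtype's blob
#' model and the mask is their exact union. All blob pixels lie strictly
#' inside the inner skull radius. The same `spec` and `seed` always give
#' bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param subtype One of [ich_subtypes()] or `"none"`.
#' @param seed Integer seed; defaults to the spec's `rng_seed`.
#' @param patient_id,slice_index Provenance metadata carried on the sample.
#' @return A [slice_sample()].
#' @export
generate_phantom_slice <- function(spec, subtype = "none", seed = spec$rng_seed,
                                   patient_id = "phantom", slice_index = 0L) {
  if (!inherits(spec, "phantom_spec")) hs_config_error("spec must be a phantom_spec")
  if (!subtype %in% c(ich_subtypes(), "none"))
    hs_config_error(sprintf("unknown subtype '%s'", subtype))
  side <- spec$side
  r <- radius_grid(side)
  ri <- spec$skull_inner * side
  ro <- spec$skull_outer * side
  withr::with_seed(as.integer(seed), {
    img <- matrix(0, side, side)
    img[r >= ri & r <= ro] <- spec$skull_level
    inside <- r < ri
    img[inside] <- spec$parenchyma_level
    mask <- matrix(0, side, side)
    if (subtype != "none") {
      model <- spec$blob_model[[subtype]]
      n <- sample(seq(model$count[1L], model$count[2L]), 1L)
      for (i in seq_len(n)) mask <- pmax(mask, draw_blob(spec, model, r, ri, side))
    }
    img <- img + spec$blob_offset * mask
    img[inside] <- img[inside] + rnorm(sum(inside), sd = spec$noise_sd)
    img <- pmin(pmax(img, 0), 1)
  })
  slice_sample(img, mask, subtype = subtype, patient_id = patient_id,
               slice_index = as.integer(slice_index))
}

#' Cohort specification for phantom generation
#'
#' Defaults mirror the study dataset: 75 scans of which 36 carry a
#' hemorrhage, roughly 30 five-millimetre slices per scan, subtype
#' frequencies 173:73:24:18:56, 46:36 male:female, and age 27.8 +/- 19.5
#' years (truncated to 1-90).
#'
#' @param n_patients Number of patients (one scan each).
#' @param ich_fraction Fraction of patients with a hemorrhage; the generated
#'   count is exact (`round(n_patients * ich_fraction)`).
#' @param slices_per_scan Mean slices per scan (Poisson, minimum 3).
#' @param subtype_weights Named relative frequencies over [ich_subtypes()];
#'   each hemorrhage slice draws its subtype from these.
#' @param pos_slices_mean Mean number of hemorrhage-bearing slices in a
#'   positive scan (Poisson, at least 1, contiguous block).
#' @param age_mean,age_sd,male_fraction Metadata distributions.
#' @param rng_seed Seed for cohort-level randomness.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 75L, ich_fraction = 36 / 75,
                        slices_per_scan = 30,
                        subtype_weights = c(epidural = 173, intraparenchymal = 73,
                                            intraventricular = 24, subarachnoid = 18,
                                            subdural = 56),
                        pos_slices_mean = 9,
                        age_mean = 27.8, age_sd = 19.5,
                        male_fraction = 46 / 82,
                        rng_seed = 1L) {
  if (n_patients < 1L) hs_config_error("n_patients must be positive")
  if (ich_fraction < 0 || ich_fraction > 1)
    hs_config_error("ich_fraction must be in [0, 1]")
  if (!all(ich_subtypes() %in% names(subtype_weights)))
    hs_config_error("subtype_weights must name all five subtypes")
  if (any(subtype_weights < 0) || sum(subtype_weights) <= 0)
    hs_config_error("subtype_weights must be non-negative and not all zero")
  structure(list(n_patients = as.integer(n_patients), ich_fraction = ich_fraction,
                 slices_per_scan = slices_per_scan,
                 subtype_weights = subtype_weights[ich_subtypes()],
                 pos_slices_mean = pos_slices_mean,
                 age_mean = age_mean, age_sd = age_sd,
                 male_fraction = male_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Generate a phantom cohort on disk
#'
#' Writes one scan NIfTI and one mask NIfTI per patient (masks use the raw
#' dataset convention of 0/255 voxels; headers record 5 mm slice spacing)
#' plus a `manifest.csv` with one row per slice. Exactly
#' `round(n_patients * ich_fraction)` patients are hemorrhage-positive, and
#' every positive patient has at least one slice with a non-empty mask.
#'
#' @param cohort A [cohort_spec()].
#' @param phantom A [phantom_spec()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest data frame (columns `patient_id`, `file_scan`,
#'   `file_mask`, `age`, `sex`, `slice_index`, `subtype`).
#' @export
generate_cohort <- function(cohort, phantom, out_dir) {
  if (!inherits(cohort, "cohort_spec")) hs_config_error("cohort must be a cohort_spec")
  if (!inherits(phantom, "phantom_spec")) hs_config_error("phantom must be a phantom_spec")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    hs_file_error(sprintf("cannot create output directory '%s'", out_dir))
  n <- cohort$n_patients
  n_pos <- round(n * cohort$ich_fraction)
  rows <- list()
  withr::with_seed(cohort$rng_seed, {
    pos <- rep(FALSE, n)
    pos[sample.int(n, n_pos)] <- TRUE
    for (p in seq_len(n)) {
      pid <- sprintf("P%03d", p)
      nz <- max(3L, rpois(1L, cohort$slices_per_scan))
      age <- round(min(max(rnorm(1L, cohort$age_mean, cohort$age_sd), 1), 90))
      sex <- sample(c("male", "female"), 1L,
                    prob = c(cohort$male_fraction, 1 - cohort$male_fraction))
      subtypes <- rep("none", nz)
      if (pos[p]) {
        k <- min(nz, max(1L, rpois(1L, cohort$pos_slices_mean)))
        start <- sample.int(nz - k + 1L, 1L)
        subtypes[start:(start + k - 1L)] <-
          sample(ich_subtypes(), k, replace = TRUE,
                 prob = cohort$subtype_weights)
      }
      scan <- array(0, c(phantom$side, phantom$side, nz))
      mask <- array(0, c(phantom$side, phantom$side, nz))
      for (z in seq_len(nz)) {
        s <- generate_phantom_slice(phantom, subtypes[z],
                                    seed = sample.int(.Machine$integer.max - 1L, 1L),
                                    patient_id = pid, slice_index = z - 1L)
        scan[, , z] <- s$image
        mask[, , z] <- s$mask * 255
      }
      f_scan <- file.path(out_dir, sprintf("%s_scan.nii.gz", pid))
      f_mask <- file.path(out_dir, sprintf("%s_mask.nii.gz", pid))
      write_ct_nifti(scan, f_scan, datatype = "double")
      write_ct_nifti(mask, f_mask, datatype = "uint8")
      rows[[p]] <- data.frame(patient_id = pid,
                              file_scan = basename(f_scan),
                              file_mask = basename(f_mask),
                              age = age, sex = sex,
                              slice_index = seq_len(nz) - 1L,
                              subtype = subtypes,
                              stringsAsFactors = FALSE)
    }
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

# NIfTI writer with the study's 5 mm slice spacing in the header.
write_ct_nifti <- function(vol, path, datatype = "double") {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(1, 1, 5)
  ok <- tryCatch({ RNifti::writeNifti(img, path, datatype = datatype); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.exists(path))
    hs_file_error(sprintf("failed to write NIfTI file '%s'", path))
  invisible(path)
}
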