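# Mask-consistent data augmentation: horizontal/vertical flips, +/-10%
# brightness, and small rotations (+10 deg, -5 deg), with per-subtype plans
# that rebalance the five hemorrhage subtypes before they are merged into a
# single "ICH" class.

#' The six augmentation operators
#'
#' Geometric operators (flips, rotations) co-transform the mask; brightness
#' operators leave it untouched.
#'
#' @return Data frame with columns `name` and `geometric`.
#' @export
augmentation_ops <- function() {
  data.frame(
    name = c("HFLIP", "VFLIP", "BRIGHT_UP_10", "BRIGHT_DOWN_10", "ROT_P10", "ROT_M5"),
    geometric = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Default per-subtype augmentation plan
#'
#' The operator lists that expand the imbalanced per-subtype slice counts
#' of the study dataset (173/73/24/18/56) to 173/219/168/126/224: the
#' abundant epidural class is left alone, the two rarest classes receive
#' all six operators, and the middle classes receive brightness and
#' rotation operators only.
#'
#' @return Named list mapping subtype to an ordered character vector of
#'   operator names.
#' @export
default_augmentation_plan <- function() {
  all6 <- augmentation_ops()$name
  list(
    epidural         = character(0),
    intraparenchymal = c("BRIGHT_UP_10", "ROT_P10"),
    intraventricular = all6,
    subarachnoid     = all6,
    subdural         = c("BRIGHT_UP_10", "BRIGHT_DOWN_10", "ROT_P10")
  )
}

#' Flip a slice and its mask
#'
#' Mirrors image and mask about the stated axis: `"horizontal"` swaps left
#' and right (columns), `"vertical"` swaps top and bottom (rows).
#'
#' @param sample A [slice_sample()].
#' @param axis `"horizontal"` or `"vertical"`.
#' @return The flipped [slice_sample()] with updated provenance.
#' @export
flip_sample <- function(sample, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  flip1 <- function(m) if (axis == "horizontal") m[, rev(seq_len(ncol(m))), drop = FALSE]
                       else m[rev(seq_len(nrow(m))), , drop = FALSE]
  out <- sample
  out$image <- flip1(sample$image)
  out$mask <- flip1(sample$mask)
  out$provenance <- if (axis == "horizontal") "hflip" else "vflip"
  out
}

#' Adjust slice brightness
#'
#' Multiplies the image by `factor` and clips to `[0, 1]`. The mask is
#' bit-identical to the input mask: brightness does not move the
#' hemorrhage.
#'
#' @param sample A [slice_sample()].
#' @param factor Positive multiplier (the default plan uses 1.10 and 0.90).
#' @return The adjusted [slice_sample()].
#' @export
adjust_brightness <- function(sample, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) || factor <= 0)
    hs_config_error("brightness factor must be a positive number")
  out <- sample
  out$image <- pmin(pmax(sample$image * factor, 0), 1)
  if (factor > 1) out$provenance <- "bright_up"
  else if (factor < 1) out$provenance <- "bright_down"
  out
}

# Rotate a matrix about its center by `degrees` (counterclockwise positive)
# using inverse mapping; out-of-frame pixels are filled with 0.
rotate_mat <- function(mat, degrees, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(mat); W <- ncol(mat)
  th <- degrees * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  dr <- matrix(rep(seq_len(H), times = W), H, W) - cr
  dc <- matrix(rep(seq_len(W), each = H), H, W) - cc
  sr <- cos(th) * dr - sin(th) * dc + cr
  sc <- sin(th) * dr + cos(th) * dc + cc
  out <- matrix(0, H, W)
  if (method == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out[ok] <- mat[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    gather <- function(ri, ci) {
      ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
      v <- numeric(length(ri))
      v[ok] <- mat[cbind(ri[ok], ci[ok])]
      v
    }
    v00 <- gather(r0, c0); v10 <- gather(r0 + 1, c0)
    v01 <- gather(r0, c0 + 1); v11 <- gather(r0 + 1, c0 + 1)
    out[] <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
             (1 - fr) * fc * v01 + fr * fc * v11
  }
  out
}

#' Rotate a slice and its mask about the image center
#'
#' The image is rotated with bilinear interpolation, the mask with
#' nearest-neighbour interpolation (so it stays binary); out-of-frame
#' pixels are filled with 0 and the output shape equals the input shape.
#'
#' @param sample A [slice_sample()].
#' @param degrees Signed rotation angle; positive is counterclockwise.
#'   Must satisfy `|degrees| < 45`.
#' @return The rotated [slice_sample()].
#' @export
rotate_sample <- function(sample, degrees) {
  if (!is.numeric(degrees) || length(degrees) != 1L || is.na(degrees) || abs(degrees) >= 45)
    hs_config_error("rotation angle must satisfy |degrees| < 45")
  out <- sample
  if (degrees != 0) {
    out$image <- rotate_mat(sample$image, degrees, "bilinear")
    out$mask <- rotate_mat(sample$mask, degrees, "nearest")
  }
  out$provenance <- if (degrees >= 0) "rot_p10" else "rot_m5"
  out
}

# Apply one named operator. The brightness-down operator acts on the
# vertically flipped image when VFLIP is also in the subtype's plan (the
# pairing used to build the augmented dataset); otherwise on the original.
apply_op <- function(sample, op, plan_ops) {
  switch(op,
    HFLIP = flip_sample(sample, "horizontal"),
    VFLIP = flip_sample(sample, "vertical"),
    BRIGHT_UP_10 = adjust_brightness(sample, 1.10),
    BRIGHT_DOWN_10 = {
      base <- if ("VFLIP" %in% plan_ops) flip_sample(sample, "vertical") else sample
      out <- adjust_brightness(base, 0.90)
      out$provenance <- "bright_down"
      out
    },
    ROT_P10 = rotate_sample(sample, 10),
    ROT_M5 = rotate_sample(sample, -5),
    hs_config_error(sprintf("unknown augmentation operator '%s'", op))
  )
}

#' Apply a per-subtype augmentation plan and merge classes
#'
#' For every input sample the output contains the original plus one
#' augmented copy per operator in its subtype's plan; all outputs are
#' relabeled to the single merged class `"ICH"`. Output order: all
#' originals first, then one block per operator (in the canonical operator
#' order), each block in input order.
#'
#' @param samples List of [slice_sample()] objects.
#' @param plan Named list mapping subtype to operator names; defaults to
#'   [default_augmentation_plan()].
#' @return List of [slice_sample()] objects of length
#'   `sum(1 + length(plan[[subtype]]))`.
#' @export
apply_plan <- function(samples, plan = default_augmentation_plan()) {
  subtypes <- vapply(samples, function(s) s$subtype, "")
  unknown <- setdiff(unique(subtypes), names(plan))
  if (length(unknown) > 0)
    hs_config_error(sprintf("plan does not cover subtype(s): %s",
                            paste(unknown, collapse = ", ")))
  bad_ops <- setdiff(unique(unlist(plan)), augmentation_ops()$name)
  if (length(bad_ops) > 0)
    hs_config_error(sprintf("plan names unknown operator(s): %s",
                            paste(bad_ops, collapse = ", ")))
  relabel <- function(s) { s$subtype <- "ICH"; s }
  out <- lapply(samples, relabel)
  for (op in augmentation_ops()$name) {
    for (i in seq_along(samples)) {
      ops_i <- plan[[subtypes[i]]]
      if (op %in% ops_i)
        out[[length(out) + 1L]] <- relabel(apply_op(samples[[i]], op, ops_i))
    }
  }
  out
}
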