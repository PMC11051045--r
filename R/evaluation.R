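# Segmentation and detection metrics: pixel confusion counts, IOU/Jaccard,
# precision/recall/F1/accuracy/specificity, object-level detection at an IOU
# threshold, pixel-pooled ROC curves with trapezoidal AUC, and demographic
# subgroup summaries.

check_binary_pair <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    hs_data_error(sprintf("prediction is %s but truth is %s",
                          paste(dim(pred), collapse = "x"),
                          paste(dim(truth), collapse = "x")))
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    hs_data_error("masks must be binary (0/1)")
}

#' Pixel-level confusion counts
#'
#' @param pred,truth Binary matrices of identical shape.
#' @return List of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
pixel_confusion <- function(pred, truth) {
  check_binary_pair(pred, truth)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn), class = "confusion_counts")
}

#' Intersection over union (Jaccard index)
#'
#' `|A n B| / |A u B|` between a predicted and a ground-truth mask. Two
#' empty masks agree perfectly and score 1; an empty mask against a
#' non-empty one scores 0.
#'
#' @param pred,truth Binary matrices of identical shape.
#' @return Fraction in `[0, 1]`.
#' @export
iou_score <- function(pred, truth) {
  check_binary_pair(pred, truth)
  inter <- sum(pred == 1 & truth == 1)
  union <- sum(pred == 1 | truth == 1)
  if (union == 0) return(1)
  inter / union
}

#' Confusion-derived metrics
#'
#' Precision, recall, F1, accuracy and specificity from pixel confusion
#' counts. Any 0/0 case returns `NA` (an explicit undefined marker), never
#' a silent 0.
#'
#' @param counts A `confusion_counts` from [pixel_confusion()], or a list
#'   with `tp`, `fp`, `tn`, `fn`.
#' @return Named list with `precision`, `recall`, `f1`, `accuracy`,
#'   `specificity`.
#' @export
seg_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0)) hs_data_error("confusion counts must be non-negative")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) NA_real_
        else 2 * precision * recall / (precision + recall)
  list(precision = precision,
       recall = recall,
       f1 = f1,
       accuracy = rat(tp + tn, tp + fp + tn + fn),
       specificity = rat(tn, tn + fp))
}

#' Label 8-connected components
#'
#' @param mask Binary matrix.
#' @return Integer matrix of component labels (background 0).
#' @export
label_components <- function(mask) {
  if (!all(mask %in% c(0, 1))) hs_data_error("mask must be binary (0/1)")
  label8_cpp(matrix(as.integer(mask), nrow(mask), ncol(mask)))
}

#' Object-level detection outcome at an IOU threshold
#'
#' Connected components (8-connectivity) of the prediction are greedily
#' matched to components of the truth in order of descending pairwise IOU.
#' A match with IOU at or above `tau` is a true positive; unmatched
#' predicted components are false positives; unmatched truth components
#' (objects the system failed to detect) are false negatives.
#'
#' @param pred,truth Binary matrices of identical shape.
#' @param tau Detection IOU threshold, default 0.5.
#' @return Named list with object counts `tp`, `fp`, `fn`.
#' @export
detection_outcome <- function(pred, truth, tau = 0.5) {
  check_binary_pair(pred, truth)
  lp <- label_components(pred)
  lt <- label_components(truth)
  np <- max(lp); nt <- max(lt)
  if (np == 0 && nt == 0) return(list(tp = 0L, fp = 0L, fn = 0L))
  if (np == 0) return(list(tp = 0L, fp = 0L, fn = nt))
  if (nt == 0) return(list(tp = 0L, fp = np, fn = 0L))
  sizes_p <- tabulate(lp[lp > 0], np)
  sizes_t <- tabulate(lt[lt > 0], nt)
  # pairwise intersections via cross-tabulation of overlapping labels
  both <- lp > 0 & lt > 0
  iou <- matrix(0, np, nt)
  if (any(both)) {
    tab <- table(factor(lp[both], levels = seq_len(np)),
                 factor(lt[both], levels = seq_len(nt)))
    inter <- matrix(as.numeric(tab), np, nt)
    uni <- outer(sizes_p, sizes_t, `+`) - inter
    iou <- inter / uni
  }
  matched_p <- logical(np); matched_t <- logical(nt); tp <- 0L
  repeat {
    iou[matched_p, ] <- -1
    iou[, matched_t] <- -1
    best <- which.max(iou)
    if (iou[best] < tau) break
    i <- (best - 1) %% np + 1; j <- (best - 1) %/% np + 1
    matched_p[i] <- TRUE; matched_t[j] <- TRUE
    tp <- tp + 1L
    if (all(matched_p) || all(matched_t)) break
  }
  list(tp = tp, fp = sum(!matched_p), fn = sum(!matched_t))
}

#' Pixel-pooled ROC curve and AUC
#'
#' Pools all pixels of the supplied probability maps and sweeps the
#' threshold over the observed probability values, producing one
#' (FPR, TPR) point per distinct threshold plus the (0,0) and (1,1)
#' endpoints; the AUC is the trapezoidal area under this curve (ties are
#' grouped, making it equal to the rank-statistic AUC).
#'
#' @param probability_maps List of numeric matrices with values in
#'   `[0, 1]`, or a single matrix/vector.
#' @param truth_masks Matching list of binary matrices (or one
#'   matrix/vector).
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(probability_maps, truth_masks) {
  if (!is.list(probability_maps)) probability_maps <- list(probability_maps)
  if (!is.list(truth_masks)) truth_masks <- list(truth_masks)
  if (length(probability_maps) != length(truth_masks))
    hs_data_error("probability_maps and truth_masks differ in length")
  p <- unlist(lapply(probability_maps, as.vector))
  y <- unlist(lapply(truth_masks, as.vector))
  if (length(p) != length(y)) hs_data_error("probability and truth shapes do not match")
  if (any(p < 0 | p > 1)) hs_data_error("probabilities must lie in [0, 1]")
  if (!all(y %in% c(0, 1))) hs_data_error("truth masks must be binary (0/1)")
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0)
    hs_data_error("ROC needs at least one positive and one negative pixel")
  o <- order(p, decreasing = TRUE)
  ps <- p[o]; ys <- y[o]
  ctp <- cumsum(ys); cfp <- cumsum(1 - ys)
  last <- c(ps[-1] != ps[-length(ps)], TRUE)   # group ties: keep last index per value
  tpr <- c(0, ctp[last] / P)
  fpr <- c(0, cfp[last] / N)
  thr <- c(Inf, ps[last])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Fold-wise ROC curves with the mean curve and mean AUC
#'
#' Computes one pixel-pooled ROC per fold, interpolates each fold's TPR on
#' a common FPR grid, and reports the pointwise mean curve together with
#' the mean of the per-fold AUCs.
#'
#' @param fold_probs List (one entry per fold) of probability-map lists.
#' @param fold_truths Matching list of truth-mask lists.
#' @param grid FPR grid for the mean curve.
#' @return List with `folds` (per-fold ROC objects), `mean_curve` (data
#'   frame `fpr`, `tpr`), and `mean_auc`.
#' @export
roc_folds <- function(fold_probs, fold_truths, grid = seq(0, 1, by = 0.01)) {
  if (length(fold_probs) != length(fold_truths))
    hs_data_error("fold lists differ in length")
  rocs <- Map(roc_curve, fold_probs, fold_truths)
  tprs <- vapply(rocs, function(r)
    approx(r$points$fpr, r$points$tpr, xout = grid, ties = max, rule = 2)$y,
    numeric(length(grid)))
  list(folds = rocs,
       mean_curve = data.frame(fpr = grid, tpr = rowMeans(as.matrix(tprs))),
       mean_auc = mean(vapply(rocs, function(r) r$auc, 0)))
}

#' Subgroup metric report
#'
#' Averages per-sample metrics within demographic groups (age threshold or
#' sex), in the layout rows = groups, columns = IOU, specificity,
#' accuracy. Groups with no members are omitted rather than reported as
#' zero.
#'
#' @param records Data frame with metric columns (`iou`, `specificity`,
#'   `accuracy`) and metadata columns (`age`, `sex`).
#' @param group_by `"age_threshold"` or `"sex"`.
#' @param age_threshold Age cut in years used when grouping by age.
#' @return Data frame with columns `group`, `n`, `iou`, `specificity`,
#'   `accuracy`.
#' @export
subgroup_report <- function(records, group_by = c("age_threshold", "sex"),
                            age_threshold = 18) {
  group_by <- match.arg(group_by)
  if (group_by == "age_threshold") {
    if (!"age" %in% names(records)) hs_data_error("records lack an 'age' column")
    grp <- ifelse(records$age < age_threshold,
                  sprintf("age < %g", age_threshold),
                  sprintf("age >= %g", age_threshold))
  } else {
    if (!"sex" %in% names(records)) hs_data_error("records lack a 'sex' column")
    grp <- as.character(records$sex)
  }
  keep <- !is.na(grp)
  records <- records[keep, , drop = FALSE]; grp <- grp[keep]
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    r <- records[grp == g, , drop = FALSE]
    data.frame(group = g, n = nrow(r),
               iou = mean(r$iou, na.rm = TRUE),
               specificity = mean(r$specificity, na.rm = TRUE),
               accuracy = mean(r$accuracy, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Evaluate predictions against truth masks
#'
#' Convenience wrapper pooling pixel confusion over a set of slices and
#' adding the mean per-slice IOU, object-level detection counts, and the
#' pooled AUC.
#'
#' @param probs List of probability matrices.
#' @param truths List of binary truth matrices.
#' @param threshold Binarization threshold for the probability maps.
#' @param tau Detection IOU threshold.
#' @return Named list of metrics.
#' @export
evaluate_predictions <- function(probs, truths, threshold = 0.5, tau = 0.5) {
  preds <- lapply(probs, function(p) (p >= threshold) * 1)
  counts <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  det <- list(tp = 0L, fp = 0L, fn = 0L)
  ious <- numeric(length(preds))
  for (i in seq_along(preds)) {
    cc <- pixel_confusion(preds[[i]], truths[[i]])
    counts <- Map(`+`, counts, cc[c("tp", "fp", "tn", "fn")])
    d <- detection_outcome(preds[[i]], truths[[i]], tau)
    det <- Map(`+`, det, d)
    ious[i] <- iou_score(preds[[i]], truths[[i]])
  }
  m <- seg_metrics(counts)
  roc <- tryCatch(roc_curve(probs, truths), error = function(e) NULL)
  c(list(iou = mean(ious),
         iou_pooled = if (counts$tp + counts$fp + counts$fn == 0) 1
                      else counts$tp / (counts$tp + counts$fp + counts$fn)),
    m,
    list(auc = if (is.null(roc)) NA_real_ else roc$auc,
         detection_tp = det$tp, detection_fp = det$fp, detection_fn = det$fn,
         counts = counts))
}

#' Per-slice metric records with metadata
#'
#' One row per slice with its IOU, specificity and accuracy plus the
#' patient metadata needed for [subgroup_report()].
#'
#' @param probs List of probability matrices.
#' @param truths List of binary truth matrices.
#' @param samples Matching list of [slice_sample()] objects (metadata
#'   source).
#' @param threshold Binarization threshold.
#' @return Data frame with one row per slice.
#' @export
slice_metric_records <- function(probs, truths, samples, threshold = 0.5) {
  do.call(rbind, lapply(seq_along(probs), function(i) {
    pred <- (probs[[i]] >= threshold) * 1
    m <- seg_metrics(pixel_confusion(pred, truths[[i]]))
    data.frame(patient_id = samples[[i]]$patient_id,
               slice_index = samples[[i]]$slice_index,
               age = samples[[i]]$age, sex = samples[[i]]$sex,
               iou = iou_score(pred, truths[[i]]),
               precision = m$precision, recall = m$recall, f1 = m$f1,
               accuracy = m$accuracy, specificity = m$specificity,
               stringsAsFactors = FALSE)
  }))
}

#' Write an overlay image of truth and predicted contours
#'
#' Renders the grayscale slice with the ground-truth mask boundary in
#' green and the predicted mask boundary in red (overlap shows yellow)
#' as an RGB PNG.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param truth,pred Binary masks.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
overlay_prediction <- function(image, truth, pred, path) {
  check_binary_pair(pred, truth)
  boundary <- function(m) {
    pad <- function(di, dj) {
      s <- matrix(0, nrow(m), ncol(m))
      ri <- seq_len(nrow(m)) + di; ci <- seq_len(ncol(m)) + dj
      ok_r <- ri >= 1 & ri <= nrow(m); ok_c <- ci >= 1 & ci <= ncol(m)
      s[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
      s
    }
    inner <- m
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      inner <- inner * pad(d[1], d[2])
    m - inner
  }
  rgb <- array(rep(pmin(pmax(image, 0), 1), 3), c(dim(image), 3))
  bt <- boundary(truth) == 1; bp <- boundary(pred) == 1
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  g[bt] <- 1; r[bt] <- pmin(r[bt], 0.2); b[bt] <- pmin(b[bt], 0.2)
  r[bp] <- 1; b[bp] <- pmin(b[bp], 0.2)
  g[bp & !bt] <- pmin(g[bp & !bt], 0.2)
  rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
  png::writePNG(rgb, path)
  invisible(path)
}

#' Plot fold-wise ROC curves
#'
#' Draws each fold's ROC, the mean curve, and the chance diagonal to a PNG
#' file.
#'
#' @param folds_roc Result of [roc_folds()].
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
plot_roc_folds <- function(folds_roc, path) {
  grDevices::png(path, width = 700, height = 700)
  on.exit(grDevices::dev.off())
  plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "False positive rate",
       ylab = "True positive rate", main = sprintf(
         "Fold-wise ROC (mean AUC = %.3f)", folds_roc$mean_auc))
  for (r in folds_roc$folds)
    lines(r$points$fpr, r$points$tpr, col = "grey60")
  lines(folds_roc$mean_curve$fpr, folds_roc$mean_curve$tpr, col = "blue", lwd = 2)
  abline(0, 1, lty = 2)
  invisible(path)
}
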