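# Metric suite: confusion counts, IOU, derived metrics, object detection,
# ROC/AUC, and subgroup reports, each checked against independent oracles.

test_that("pixel confusion matches hand-computed and brute-force values", {
  ones <- matrix(1, 10, 10)
  cc <- pixel_confusion(ones, ones)
  expect_equal(cc[c("tp", "fp", "tn", "fn")], list(tp = 100, fp = 0, tn = 0, fn = 0))

  truth <- matrix(0, 10, 10); truth[1, 1:7] <- 1
  cc2 <- pixel_confusion(matrix(0, 10, 10), truth)
  expect_equal(cc2$fn, 7); expect_equal(cc2$tn, 93)

  set.seed(7)
  for (i in 1:10) {
    p <- random_mask(32); t <- random_mask(32)
    expect_equal(unclass(pixel_confusion(p, t))[c("tp", "fp", "tn", "fn")],
                 confusion_oracle(p, t)[c("tp", "fp", "tn", "fn")])
  }
  expect_error(pixel_confusion(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "hemoseg_data_error")
  expect_error(pixel_confusion(matrix(2, 2, 2), matrix(0, 2, 2)),
               class = "hemoseg_data_error")
})

test_that("IOU follows the set formula with the empty-mask conventions", {
  m <- matrix(0, 8, 8); m[2:5, 2:5] <- 1
  expect_equal(iou_score(m, m), 1)
  disj <- matrix(0, 8, 8); disj[7:8, 7:8] <- 1
  expect_equal(iou_score(m, disj), 0)
  # truth = 2k block, pred = half of it plus k disjoint pixels -> 1/3
  k <- 4L
  truth <- matrix(0, 10, 10); truth[1, 1:(2 * k)] <- 1
  pred <- matrix(0, 10, 10); pred[1, 1:k] <- 1; pred[5, 1:k] <- 1
  expect_equal(iou_score(pred, truth), 1 / 3)
  # conventions
  empty <- matrix(0, 8, 8)
  expect_equal(iou_score(empty, empty), 1)
  expect_equal(iou_score(empty, m), 0)
  expect_equal(iou_score(m, empty), 0)
})

test_that("derived metrics match direct substitution and flag 0/0 as NA", {
  m <- seg_metrics(list(tp = 8, fp = 2, fn = 2, tn = 88))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$accuracy, 0.96)
  expect_equal(m$specificity, 88 / 90)

  perfect <- seg_metrics(list(tp = 5, fp = 0, fn = 0, tn = 95))
  expect_equal(unlist(perfect[c("precision", "recall", "f1")]),
               c(precision = 1, recall = 1, f1 = 1))

  undef <- seg_metrics(list(tp = 0, fp = 0, fn = 3, tn = 97))
  expect_true(is.na(undef$precision))
  expect_false(is.na(undef$recall))
})

test_that("metrics and IOU agree with brute-force oracles on random masks", {
  set.seed(11)
  for (i in 1:200) {
    p <- random_mask(8, runif(1, 0.1, 0.9))
    t <- random_mask(8, runif(1, 0.1, 0.9))
    expect_equal(iou_score(p, t), iou_oracle(p, t), tolerance = 1e-12)
    cc <- pixel_confusion(p, t); oc <- confusion_oracle(p, t)
    m <- seg_metrics(cc)
    if (oc$tp + oc$fp > 0) expect_equal(m$precision, oc$tp / (oc$tp + oc$fp), tolerance = 1e-12)
    if (oc$tp + oc$fn > 0) expect_equal(m$recall, oc$tp / (oc$tp + oc$fn), tolerance = 1e-12)
    if (oc$tn + oc$fp > 0) expect_equal(m$specificity, oc$tn / (oc$tn + oc$fp), tolerance = 1e-12)
    expect_equal(m$accuracy, (oc$tp + oc$tn) / 64, tolerance = 1e-12)
  }
})

test_that("growing a prediction toward the truth never decreases IOU", {
  set.seed(3)
  truth <- matrix(0, 16, 16); truth[4:12, 4:12] <- 1
  pred <- truth; missing <- which(truth == 1)
  pred[missing[1:40]] <- 0
  prev <- iou_score(pred, truth)
  for (px in missing[1:40]) {
    pred[px] <- 1
    cur <- iou_score(pred, truth)
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_equal(prev, 1)
})

test_that("component labelling uses 8-connectivity", {
  m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1   # diagonal touch
  expect_equal(max(label_components(m)), 1)
  m2 <- matrix(0, 4, 4); m2[1, 1] <- 1; m2[3, 3] <- 1 # gap of one
  expect_equal(max(label_components(m2)), 2)
})

test_that("detection outcomes follow the IOU >= 0.5 matching rule", {
  truth <- matrix(0, 20, 20); truth[3:8, 3:8] <- 1
  expect_equal(detection_outcome(truth, truth), list(tp = 1L, fp = 0L, fn = 0L))
  # missed object: empty prediction is a false negative
  expect_equal(detection_outcome(matrix(0, 20, 20), truth),
               list(tp = 0L, fp = 0L, fn = 1L))
  # spurious object: prediction with no truth is a false positive
  expect_equal(detection_outcome(truth, matrix(0, 20, 20)),
               list(tp = 0L, fp = 1L, fn = 0L))
  # overlap below threshold: 6x6 truth vs prediction shifted to IOU = 0.4ish
  pred <- matrix(0, 20, 20); pred[6:11, 3:8] <- 1   # overlap 3 rows of 6 = 18
  iou_pair <- 18 / (36 + 36 - 18)
  expect_lt(iou_pair, 0.5)
  expect_equal(detection_outcome(pred, truth), list(tp = 0L, fp = 1L, fn = 1L))
  # two objects, one found
  truth2 <- truth; truth2[14:17, 14:17] <- 1
  expect_equal(detection_outcome(truth, truth2), list(tp = 1L, fp = 0L, fn = 1L))
})

test_that("ROC endpoints, chance level, and rank-statistic equivalence hold", {
  truth <- matrix(rbinom(100, 1, 0.3), 10, 10)
  r1 <- roc_curve(truth * 1.0, truth)
  expect_equal(r1$auc, 1)
  r2 <- roc_curve(matrix(0.5, 10, 10), truth)
  expect_equal(r2$auc, 0.5)
  set.seed(5)
  for (i in 1:20) {
    p <- matrix(runif(64), 8, 8)
    if (i %% 2 == 0) p <- round(p, 1)  # force ties
    y <- random_mask(8, 0.35)
    if (sum(y) == 0 || sum(y) == 64) next
    r <- roc_curve(p, y)
    expect_equal(r$auc, auc_rank_oracle(as.vector(p), as.vector(y)),
                 tolerance = 1e-9)
  }
})

test_that("ROC matches pROC on a random probability map", {
  skip_if_not_installed("pROC")
  set.seed(9)
  p <- runif(500); y <- rbinom(500, 1, 0.4)
  ours <- roc_curve(matrix(p, 20, 25), matrix(y, 20, 25))$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("fold-wise ROC reports per-fold curves, mean curve and mean AUC", {
  set.seed(13)
  fold_p <- lapply(1:3, function(i) list(matrix(runif(64), 8, 8)))
  fold_t <- lapply(1:3, function(i) list(random_mask(8, 0.4)))
  fr <- roc_folds(fold_p, fold_t)
  expect_length(fr$folds, 3)
  expect_equal(fr$mean_auc, mean(vapply(fr$folds, function(r) r$auc, 0)))
  expect_equal(nrow(fr$mean_curve), 101)
  expect_true(all(diff(fr$mean_curve$tpr) >= -1e-12))
})

test_that("subgroup reports aggregate correctly and omit empty groups", {
  rec <- data.frame(age = c(10, 15, 40, 60), sex = c("male", "female", "male", "female"),
                    iou = c(0.9, 0.8, 0.7, 0.6),
                    specificity = c(0.99, 0.98, 0.97, 0.96),
                    accuracy = c(0.95, 0.94, 0.93, 0.92))
  by_age <- subgroup_report(rec, "age_threshold", age_threshold = 18)
  expect_equal(nrow(by_age), 2)
  expect_equal(sum(by_age$n), nrow(rec))
  expect_equal(by_age$iou[by_age$group == "age < 18"], 0.85)
  # single group: grouped value equals the global mean
  young <- subgroup_report(rec[rec$age < 18, ], "age_threshold")
  expect_equal(nrow(young), 1)
  expect_equal(young$iou, mean(rec$iou[rec$age < 18]))
  # two equal-size groups: global mean is the average of group means
  by_sex <- subgroup_report(rec, "sex")
  expect_equal(mean(by_sex$iou), mean(rec$iou))
})

test_that("overlay images mark truth and prediction boundaries", {
  dir <- withr::local_tempdir()
  s <- generate_phantom_slice(tiny_phantom(32), "epidural", seed = 2)
  pred <- s$mask
  p <- overlay_prediction(s$image, s$mask, pred, file.path(dir, "o.png"))
  expect_true(file.exists(p))
  img <- png::readPNG(p)
  expect_equal(dim(img), c(32L, 32L, 3L))
  # perfect prediction: boundary pixels are yellow (red+green, low blue)
  expect_gt(sum(img[, , 1] == 1 & img[, , 2] == 1 & img[, , 3] <= 0.21), 0)
})

test_that("recall complements the miss rate and specificity the false-positive rate", {
  set.seed(17)
  for (i in 1:20) {
    cc <- confusion_oracle(random_mask(8), random_mask(8))
    m <- seg_metrics(cc)
    if (!is.na(m$recall))
      expect_equal(m$recall + cc$fn / (cc$tp + cc$fn), 1, tolerance = 1e-12)
    if (!is.na(m$specificity))
      expect_equal(m$specificity + cc$fp / (cc$tn + cc$fp), 1, tolerance = 1e-12)
  }
})
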