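# Training with the study protocol: Adam (learning rate 0.001, batch 16)
# on a binary cross-entropy + Dice loss, under k-fold (default 10)
# cross-validation with per-fold metric records.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (study value: 0.001).
#' @param batch_size Mini-batch size (study value: 16).
#' @param epochs Number of passes over the training set.
#' @param loss `"bce_plus_dice"` (default), `"binary_cross_entropy"`, or
#'   `"dice"`.
#' @param seed Seed controlling weight initialisation and batch shuffling.
#' @param threshold Probability threshold for mask binarization.
#' @param early_stop_patience If finite, stop when the epoch training loss
#'   has not improved for this many epochs.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 16L, epochs = 10L,
                         loss = c("bce_plus_dice", "binary_cross_entropy", "dice"),
                         seed = 1L, threshold = 0.5,
                         early_stop_patience = Inf) {
  loss <- match.arg(loss)
  if (learning_rate <= 0) hs_config_error("learning_rate must be positive")
  if (batch_size < 1L) hs_config_error("batch_size must be at least 1")
  if (epochs < 1L) hs_config_error("epochs must be at least 1")
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 loss = loss, seed = as.integer(seed), threshold = threshold,
                 early_stop_patience = early_stop_patience),
            class = "train_config")
}

#' Partition sample ids into k cross-validation folds
#'
#' A seeded random permutation split into k near-equal folds (sizes differ
#' by at most one); deterministic given the seed.
#'
#' @param sample_ids Vector of sample identifiers.
#' @param k Number of folds, default 10.
#' @param seed Integer seed.
#' @return Object of class `fold_split`: list with `k` and `assignments`
#'   (named integer vector mapping id to fold in `1..k`).
#' @export
make_folds <- function(sample_ids, k = 10L, seed = 1L) {
  n <- length(sample_ids)
  if (n < k) hs_data_error(sprintf("cannot split %d samples into %d folds", n, k))
  if (anyDuplicated(sample_ids)) hs_data_error("sample_ids must be unique")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  fold <- integer(n)
  # fold sizes n %/% k (+1 for the first n %% k folds)
  fold[perm] <- rep(seq_len(k), times = c(rep(n %/% k + 1L, n %% k),
                                          rep(n %/% k, k - n %% k)))
  structure(list(k = as.integer(k),
                 assignments = setNames(fold, as.character(sample_ids))),
            class = "fold_split")
}

# Stack samples into input/target tensors for one mini-batch.
batch_tensors <- function(samples, idx, channels) {
  x <- stack_input(lapply(idx, function(i) samples[[i]]$image), channels)
  d <- dim(samples[[idx[1L]]]$image)
  t <- array(0, c(d[1L], d[2L], 1L, length(idx)))
  for (j in seq_along(idx)) t[, , 1L, j] <- samples[[idx[j]]]$mask
  list(x = x, target = t)
}

#' Train the segmentation model on a set of slices
#'
#' Re-initialises the model from `config$seed`, then runs
#' `config$epochs` epochs of shuffled mini-batch Adam updates on the
#' combined loss. A non-finite loss aborts with a training error naming
#' the epoch.
#'
#' @param model_spec A [residual_unet_spec()].
#' @param train_samples Non-empty list of [slice_sample()] objects whose
#'   image side matches the spec.
#' @param config A [train_config()].
#' @param verbose Print per-epoch loss?
#' @return List with `model` (trained `hs_model`), `history` (mean loss per
#'   epoch), and `n_steps` (total optimizer updates).
#' @export
train_fold <- function(model_spec, train_samples, config = train_config(),
                       verbose = FALSE) {
  if (length(train_samples) == 0L) hs_data_error("training set is empty")
  model <- build_model(model_spec, seed = config$seed)
  n <- length(train_samples)
  plist <- mget(ls(model$params), envir = model$params)
  history <- numeric(0)
  n_steps <- 0L
  best <- Inf; stall <- 0L
  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      losses <- numeric(length(starts))
      for (b in seq_along(starts)) {
        idx <- ord[starts[b]:min(starts[b] + config$batch_size - 1L, n)]
        bt <- batch_tensors(train_samples, idx, model$spec$input_channels)
        fw <- model_forward(model, bt$x, training = TRUE)
        lo <- seg_loss(fw$prob$value, bt$target, config$loss)
        if (!is.finite(lo$loss))
          hs_train_error(sprintf("non-finite loss at epoch %d", epoch))
        ag_backward(fw$tape, fw$logit, lo$dlogit)
        n_steps <- n_steps + 1L
        adam_step(plist, config$learning_rate, n_steps)
        losses[b] <- lo$loss
      }
      history[epoch] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %d/%d loss %.4f", epoch, config$epochs, history[epoch]))
      if (history[epoch] < best - 1e-6) { best <- history[epoch]; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= config$early_stop_patience) break
    }
  })
  list(model = model, history = history, n_steps = n_steps)
}

# Evaluate a trained model on a held-out set of slices: predicted
# probability maps in small batches, then the pooled metric record.
eval_on_samples <- function(model, samples, threshold = 0.5, batch = 8L) {
  probs <- list()
  for (s in seq(1L, length(samples), by = batch)) {
    idx <- s:min(s + batch - 1L, length(samples))
    probs <- c(probs, predict_prob(model, lapply(idx, function(i) samples[[i]]$image)))
  }
  truths <- lapply(samples, function(s) s$mask)
  list(probs = probs, truths = truths,
       metrics = evaluate_predictions(probs, truths, threshold = threshold))
}

#' k-fold cross-validated training and evaluation
#'
#' Splits the slices into k folds (optionally stratified so that no
#' patient's slices straddle train and validation), trains a fresh model
#' on each k-1 fold training set, evaluates on the held-out fold, and
#' aggregates per-fold metrics as mean and population standard deviation.
#'
#' @param samples List of [slice_sample()] objects.
#' @param model_spec A [residual_unet_spec()].
#' @param config A [train_config()].
#' @param k Number of folds, default 10.
#' @param by_patient Assign whole patients to folds instead of slices?
#' @param verbose Print fold progress?
#' @return Object of class `cv_report`: list with `folds` (data frame of
#'   per-fold metrics), `mean`, `sd`, `split` (the `fold_split`), and
#'   `roc` (the [roc_folds()] result).
#' @export
cross_validate <- function(samples, model_spec, config = train_config(),
                           k = 10L, by_patient = FALSE, verbose = FALSE) {
  n <- length(samples)
  ids <- as.character(seq_len(n))
  if (by_patient) {
    pats <- vapply(samples, function(s) as.character(s$patient_id), "")
    psplit <- make_folds(unique(pats), k = k, seed = config$seed)
    fold_of <- psplit$assignments[pats]
    split <- structure(list(k = as.integer(k),
                            assignments = setNames(as.integer(fold_of), ids)),
                       class = "fold_split")
  } else {
    split <- make_folds(ids, k = k, seed = config$seed)
  }
  metric_cols <- c("iou", "iou_pooled", "precision", "recall", "f1",
                   "accuracy", "specificity", "auc",
                   "detection_tp", "detection_fp", "detection_fn")
  rows <- list(); fold_probs <- list(); fold_truths <- list()
  for (f in seq_len(k)) {
    val_idx <- which(split$assignments == f)
    train_idx <- setdiff(seq_len(n), val_idx)
    if (length(val_idx) == 0L || length(train_idx) == 0L)
      hs_data_error(sprintf("fold %d has an empty train or validation set", f))
    if (verbose) message(sprintf("fold %d/%d: %d train / %d validation",
                                 f, k, length(train_idx), length(val_idx)))
    tr <- train_fold(model_spec, samples[train_idx], config)
    ev <- eval_on_samples(tr$model, samples[val_idx], threshold = config$threshold)
    fold_probs[[f]] <- ev$probs
    fold_truths[[f]] <- ev$truths
    rows[[f]] <- data.frame(fold = f,
                            n_val = length(val_idx),
                            as.data.frame(ev$metrics[metric_cols]),
                            final_loss = tr$history[length(tr$history)])
  }
  folds <- do.call(rbind, rows)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  roc <- tryCatch(roc_folds(fold_probs, fold_truths), error = function(e) NULL)
  structure(list(folds = folds,
                 mean = colMeans(folds[metric_cols]),
                 sd = vapply(folds[metric_cols], pop_sd, 0),
                 split = split,
                 roc = roc),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds\n", nrow(x$folds)))
  for (m in c("iou", "recall", "specificity", "accuracy", "auc"))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}
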