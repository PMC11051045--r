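# Shared fixtures: tiny phantom specs, random binary masks, and independent
# oracles (per-pixel confusion loop, set-arithmetic IOU, rank-statistic AUC,
# Otsu threshold) used to cross-check the package's metric implementations.

tiny_phantom <- function(side = 32L, seed = 1L) phantom_spec(side = side, rng_seed = seed)

phantom_batch <- function(n, side = 32L, subtypes = NULL, seed0 = 100L) {
  ps <- phantom_spec(side = side)
  if (is.null(subtypes))
    subtypes <- rep(ich_subtypes(), length.out = n)
  lapply(seq_len(n), function(i)
    generate_phantom_slice(ps, subtypes[i], seed = seed0 + i))
}

random_mask <- function(side = 8L, p = 0.4) {
  matrix(rbinom(side * side, 1, p), side, side)
}

# Independent per-pixel confusion oracle (explicit double loop).
confusion_oracle <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
    else if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1
    else if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Set-arithmetic IOU oracle on pixel index sets.
iou_oracle <- function(pred, truth) {
  a <- which(pred == 1); b <- which(truth == 1)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# Rank-statistic (Mann-Whitney) AUC oracle with tie handling.
auc_rank_oracle <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Otsu threshold on a vector of intensities in [0, 1] (256-bin histogram);
# used as the separability oracle for phantom slices.
otsu_threshold <- function(v) {
  h <- tabulate(pmin(pmax(floor(v * 255), 0), 255) + 1L, 256L)
  w <- h / sum(h)
  lev <- (0:255) / 255
  best <- -1; thr <- 0.5
  for (k in 1:255) {
    w0 <- sum(w[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(w[1:k] * lev[1:k]) / w0
    m1 <- sum(w[(k + 1):256] * lev[(k + 1):256]) / w1
    between <- w0 * w1 * (m0 - m1)^2
    if (between > best) { best <- between; thr <- lev[k] }
  }
  thr
}

# Tiny model spec used across architecture tests.
tiny_spec <- function(side = 32L, levels = 3L, channels = c(4L, 8L, 16L), ...) {
  residual_unet_spec(input_side = side, n_levels = levels,
                     channel_schedule = channels, ...)
}
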