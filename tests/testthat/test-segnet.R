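# Architecture contracts of the residual U-Net.

test_that("spec validation enforces the side/levels divisibility and schedules", {
  expect_error(residual_unet_spec(input_side = 100),
               "divisible", class = "hemoseg_config_error")
  expect_error(residual_unet_spec(channel_schedule = c(16L, 32L)),
               "n_levels", class = "hemoseg_config_error")
  expect_error(residual_unet_spec(convs_per_residual_block = 0L),
               class = "hemoseg_config_error")
  sp <- residual_unet_spec()
  expect_equal(sp$input_side / 2^(sp$n_levels - 1), 64)  # 512 -> 64 over 4 levels
  expect_equal(sp$channel_schedule[sp$n_levels], 128L)
})

test_that("the model conserves spatial shape and emits sigmoid-range outputs", {
  for (cfg in list(list(side = 32L, lv = 3L, ch = c(4L, 8L, 16L)),
                   list(side = 64L, lv = 4L, ch = c(4L, 6L, 8L, 12L)))) {
    spec <- residual_unet_spec(input_side = cfg$side, n_levels = cfg$lv,
                               channel_schedule = cfg$ch)
    m <- build_model(spec, seed = 2)
    img <- matrix(runif(cfg$side^2), cfg$side, cfg$side)
    p <- predict_prob(m, list(img))[[1]]
    expect_equal(dim(p), c(cfg$side, cfg$side))
    expect_true(min(p) > 0 && max(p) < 1)
  }
})

test_that("inference is deterministic: same weights and input give identical output", {
  spec <- tiny_spec()
  m <- build_model(spec, seed = 5)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predict_prob(m, list(img)), predict_prob(m, list(img)))
})

test_that("a shape-preserving residual block with zeroed branch weights is the identity", {
  # level-1 block of a 3->3 schedule is in==out, stride 1 (identity shortcut)
  spec <- residual_unet_spec(input_side = 16L, n_levels = 2L,
                             channel_schedule = c(3L, 6L))
  m <- build_model(spec, seed = 1)
  for (nm in ls(m$params)) {
    if (startsWith(nm, "enc1.c")) m$params[[nm]]$value[] <- 0
  }
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))  # non-negative input
  fw <- hemoseg:::model_forward(m, x, training = FALSE)
  out_id <- grep("^enc1.*relu$", names(fw$nodes), value = TRUE)
  out_id <- out_id[length(out_id)]
  expect_equal(fw$nodes[[out_id]]$value, x, tolerance = 1e-12)
})

test_that("residual blocks contain exactly n convolutions plus at most one projection", {
  blk <- build_residual_block(8, 8, downsample = FALSE, n_convs = 3L)
  ops <- vapply(blk, function(n) n$op, "")
  expect_equal(sum(ops == "conv"), 3L)  # identity shortcut: no projection
  blk2 <- build_residual_block(8, 16, downsample = TRUE, n_convs = 3L)
  ops2 <- vapply(blk2, function(n) n$op, "")
  expect_equal(sum(ops2 == "conv"), 4L) # 3 branch convs + 1x1 projection
  proj <- blk2[["block.proj.conv"]]
  expect_equal(proj$kh, 1L)
  expect_equal(proj$stride, 2L)
})

test_that("parameter count grows with depth, width, and convs per block", {
  base <- count_params(build_model(tiny_spec(), seed = 1))
  deeper <- count_params(build_model(
    residual_unet_spec(input_side = 32L, n_levels = 4L,
                       channel_schedule = c(4L, 8L, 16L, 32L)), seed = 1))
  wider <- count_params(build_model(
    residual_unet_spec(input_side = 32L, n_levels = 3L,
                       channel_schedule = c(8L, 16L, 32L)), seed = 1))
  slimmer <- count_params(build_model(
    residual_unet_spec(input_side = 32L, n_levels = 3L,
                       channel_schedule = c(4L, 8L, 16L),
                       convs_per_residual_block = 1L), seed = 1))
  expect_gt(deeper, base)
  expect_gt(wider, base)
  expect_gt(base, slimmer)
})

test_that("plain_skip wiring reduces to standard U-Net concatenation skips", {
  g_ida <- model_graph(build_model(tiny_spec(aggregation = "iterative_deep"), seed = 1))
  g_un <- model_graph(build_model(tiny_spec(aggregation = "plain_skip"), seed = 1))
  # U-Net: concat skips present, no aggregation-sum nodes
  expect_true(any(g_un$op == "concat"))
  expect_false(any(grepl("^agg", g_un$id)))
  # each decoder level concatenates the upsampled deeper map with the
  # same-level encoder output
  cats <- g_un[g_un$op == "concat", ]
  expect_equal(nrow(cats), 2L)  # 3 levels -> 2 decoder nodes
  expect_true(all(grepl("enc", cats$inputs)))
  # deep aggregation: three-input fusion nodes, no concatenation
  expect_false(any(g_ida$op == "concat"))
  sums <- g_ida[grepl("^agg[0-9]+[.]sum$", g_ida$id), ]
  expect_equal(nrow(sums), 2L)
  expect_true(all(vapply(strsplit(sums$inputs, ","), length, 0L) == 3L))
})

test_that("the resnet34 backbone builds the standard 34-layer encoder layout", {
  spec <- residual_unet_spec(input_side = 64L, backbone = "resnet34")
  m <- build_model(spec, seed = 1)
  g <- model_graph(m)
  # stages of 3, 4, 6, 3 basic blocks
  for (st in 1:4) {
    ids <- grep(sprintf("^layer%d[.]b[0-9]+[.]", st), g$id, value = TRUE)
    blocks <- unique(sub("^(layer[0-9]+[.]b[0-9]+)[.].*$", "\\1", ids))
    expect_length(blocks, c(3L, 4L, 6L, 3L)[st])
  }
  expect_true("stem.pool" %in% g$id)
  img <- matrix(runif(64 * 64), 64, 64)
  p <- predict_prob(m, list(img))[[1]]
  expect_equal(dim(p), c(64L, 64L))
})

test_that("predict_mask thresholds the probability map into a binary mask", {
  m <- build_model(tiny_spec(), seed = 3)
  img <- matrix(runif(32 * 32), 32, 32)
  mask <- predict_mask(m, img)
  expect_true(all(mask %in% c(0, 1)))
  expect_equal(predict_mask(m, img, threshold = 0), matrix(1, 32, 32))
  p <- predict_prob(m, list(img))[[1]]
  expect_identical(predict_mask(m, img, threshold = 0.5), (p >= 0.5) * 1)
  expect_error(predict_mask(m, matrix(0, 16, 16)), class = "hemoseg_data_error")
})

test_that("feature aggregation resamples to the finest input and preserves shape", {
  a <- array(rnorm(8 * 8 * 4 * 1), c(8, 8, 4, 1))
  f1 <- aggregate_features(list(a, a))
  expect_equal(dim(f1)[1:2], c(8L, 8L))
  b <- array(rnorm(16 * 16 * 2 * 1), c(16, 16, 2, 1))
  f2 <- aggregate_features(list(a, b))
  expect_equal(dim(f2)[1:2], c(16L, 16L))
  expect_equal(dim(f2)[3], 2L)   # finest input's channels by default
  expect_error(aggregate_features(list()), class = "hemoseg_config_error")
})

test_that("autograd gradients match finite differences through the whole net", {
  spec <- residual_unet_spec(input_side = 8L, n_levels = 2L,
                             channel_schedule = c(2L, 3L),
                             convs_per_residual_block = 2L)
  m <- build_model(spec, seed = 4)
  set.seed(4)
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  t <- array(rbinom(128, 1, 0.3), c(8, 8, 1, 2))
  loss_at <- function() {
    fw <- hemoseg:::model_forward(m, x, training = TRUE)
    hemoseg:::seg_loss(fw$prob$value, t, "bce_plus_dice")$loss
  }
  fw <- hemoseg:::model_forward(m, x, training = TRUE)
  lo <- hemoseg:::seg_loss(fw$prob$value, t, "bce_plus_dice")
  hemoseg:::ag_backward(fw$tape, fw$logit, lo$dlogit)
  for (nm in c("enc1.c1.conv.w", "enc2.c1.conv.w", "agg1.fuse.conv.w",
               "head.conv.w", "enc1.c1.bn.gamma")) {
    p <- m$params[[nm]]
    i <- sample(length(p$value), 1)
    e <- 1e-5
    old <- p$value[i]
    # BN running stats drift across calls; gradients only need the batch stats,
    # which depend on the weights, so re-evaluate the full forward each time.
    p$value[i] <- old + e; up <- loss_at()
    p$value[i] <- old - e; dn <- loss_at()
    p$value[i] <- old
    expect_equal(p$grad[i], (up - dn) / (2 * e), tolerance = 1e-4,
                 label = sprintf("grad of %s", nm))
  }
})

test_that("model checkpoints round-trip through save and load", {
  dir <- withr::local_tempdir()
  m <- build_model(tiny_spec(), seed = 6)
  img <- matrix(runif(32 * 32), 32, 32)
  p1 <- predict_prob(m, list(img))[[1]]
  save_model(m, file.path(dir, "m.rds"))
  m2 <- load_model(file.path(dir, "m.rds"))
  expect_equal(predict_prob(m2, list(img))[[1]], p1)
  expect_error(load_model(file.path(dir, "missing.rds")), class = "hemoseg_file_error")
})
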