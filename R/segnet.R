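# Residual U-Net with deep feature aggregation.
#
# The architecture is described as a flat operation graph (a list of nodes,
# each naming its op, its inputs and its shape parameters). Both parameter
# initialisation and the forward pass interpret this graph, which also gives
# an exportable structural description for wiring tests.

#' Residual U-Net architecture specification
#'
#' Describes the segmentation network: a contracting encoder of residual
#' blocks (three convolutions per block by default, plus an identity or 1x1
#' projection shortcut), a decoder that either aggregates features across
#' depths iteratively (`"iterative_deep"`) or uses plain U-Net concatenation
#' skips (`"plain_skip"`), and a per-pixel sigmoid head. With the defaults
#' the spatial size halves at each of the deeper levels (512 to 64 over four
#' levels) while channels grow from 3 to 128.
#'
#' @param input_side Input image side in pixels (square input).
#' @param input_channels Number of input channels; grayscale slices are
#'   replicated to 3 channels before the forward pass.
#' @param n_levels Number of encoder resolution levels.
#' @param channel_schedule Channel count per level, one entry per level.
#' @param convs_per_residual_block Convolutions in each residual branch.
#' @param aggregation `"iterative_deep"` for deep feature aggregation,
#'   `"plain_skip"` for standard U-Net concatenation skips.
#' @param backbone `"custom_residual"` for the block structure above, or
#'   `"resnet34"` for the standard 34-layer residual encoder layout.
#' @return An object of class `residual_unet_spec`.
#' @export
residual_unet_spec <- function(input_side = 512L,
                               input_channels = 3L,
                               n_levels = 4L,
                               channel_schedule = c(16L, 32L, 64L, 128L),
                               convs_per_residual_block = 3L,
                               aggregation = c("iterative_deep", "plain_skip"),
                               backbone = c("custom_residual", "resnet34")) {
  aggregation <- match.arg(aggregation)
  backbone <- match.arg(backbone)
  if (length(channel_schedule) != n_levels)
    hs_config_error(sprintf(
      "channel_schedule has %d entries but n_levels is %d",
      length(channel_schedule), n_levels))
  if (n_levels < 2L) hs_config_error("n_levels must be at least 2")
  if (any(channel_schedule < 1L)) hs_config_error("channel counts must be positive")
  if (convs_per_residual_block < 1L)
    hs_config_error("convs_per_residual_block must be at least 1")
  div <- if (backbone == "resnet34") 32L else 2L^(n_levels - 1L)
  if (input_side %% div != 0L)
    hs_config_error(sprintf(
      "input_side %d is not divisible by %d (required by the %s backbone)",
      input_side, div, backbone))
  structure(list(
    input_side = as.integer(input_side),
    input_channels = as.integer(input_channels),
    n_levels = as.integer(n_levels),
    channel_schedule = as.integer(channel_schedule),
    convs_per_residual_block = as.integer(convs_per_residual_block),
    aggregation = aggregation,
    backbone = backbone,
    output_activation = "sigmoid"
  ), class = "residual_unet_spec")
}

# ---- graph construction ----------------------------------------------------

gb_new <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g
}

gb_add <- function(g, id, op, inputs = character(), in_ch = NA_integer_,
                   out_ch = NA_integer_, kh = NA_integer_, stride = NA_integer_,
                   pad = NA_integer_) {
  g$nodes[[id]] <- list(id = id, op = op, inputs = inputs,
                        in_ch = in_ch, out_ch = out_ch,
                        kh = kh, stride = stride, pad = pad)
  id
}

# conv -> bn [-> relu]; returns the id of the last node added.
gb_cbr <- function(g, base, input, in_ch, out_ch, k = 3L, stride = 1L, relu = TRUE) {
  pad <- (k - 1L) %/% 2L
  c1 <- gb_add(g, paste0(base, ".conv"), "conv", input, in_ch, out_ch, k, stride, pad)
  b1 <- gb_add(g, paste0(base, ".bn"), "bn", c1, out_ch, out_ch)
  if (relu) gb_add(g, paste0(base, ".relu"), "relu", b1, out_ch, out_ch) else b1
}

#' Describe one residual block
#'
#' A residual block computes `F(x) + shortcut(x)` where `F` is a stack of
#' `n_convs` conv/batch-norm/rectifier stages and the shortcut is the
#' identity when shapes match, else a 1x1 projection. The spatial size
#' halves iff `downsample`.
#'
#' @param in_channels,out_channels Channel counts in and out.
#' @param downsample Halve the spatial size (stride-2 first convolution)?
#' @param n_convs Convolutions in the residual branch.
#' @return A list describing the block's layers (op graph fragment).
#' @export
build_residual_block <- function(in_channels, out_channels, downsample = FALSE,
                                 n_convs = 3L) {
  if (in_channels < 1L || out_channels < 1L)
    hs_config_error("channel counts must be positive")
  g <- gb_new()
  gb_add(g, "in", "input", character(), out_ch = in_channels)
  gb_res_block(g, "block", "in", in_channels, out_channels,
               if (downsample) 2L else 1L, n_convs)
  g$nodes
}

# Residual block nodes appended to graph g; returns output id.
gb_res_block <- function(g, base, input, in_ch, out_ch, stride, n_convs) {
  x <- input
  cur_in <- in_ch
  for (i in seq_len(n_convs)) {
    s <- if (i == 1L) stride else 1L
    last <- i == n_convs
    x <- gb_cbr(g, paste0(base, ".c", i), x, cur_in, out_ch, 3L, s, relu = !last)
    cur_in <- out_ch
  }
  short <- if (in_ch == out_ch && stride == 1L) {
    input
  } else {
    c1 <- gb_add(g, paste0(base, ".proj.conv"), "conv", input, in_ch, out_ch,
                 1L, stride, 0L)
    gb_add(g, paste0(base, ".proj.bn"), "bn", c1, out_ch, out_ch)
  }
  s1 <- gb_add(g, paste0(base, ".add"), "add", c(x, short), out_ch, out_ch)
  gb_add(g, paste0(base, ".relu"), "relu", s1, out_ch, out_ch)
}

# Align a map to `out_ch` channels with a 1x1 conv + bn.
gb_align <- function(g, base, input, in_ch, out_ch) {
  c1 <- gb_add(g, paste0(base, ".conv"), "conv", input, in_ch, out_ch, 1L, 1L, 0L)
  gb_add(g, paste0(base, ".bn"), "bn", c1, out_ch, out_ch)
}

# Encoder for the custom residual backbone: list of (id, channels) per level.
gb_encoder_custom <- function(g, spec) {
  enc <- vector("list", spec$n_levels)
  x <- gb_add(g, "input", "input", character(), out_ch = spec$input_channels)
  in_ch <- spec$input_channels
  for (d in seq_len(spec$n_levels)) {
    out_ch <- spec$channel_schedule[d]
    x <- gb_res_block(g, sprintf("enc%d", d), x, in_ch, out_ch,
                      if (d == 1L) 1L else 2L, spec$convs_per_residual_block)
    enc[[d]] <- list(id = x, ch = out_ch)
    in_ch <- out_ch
  }
  enc
}

# Standard 34-layer residual encoder: 7x7/2 stem, 3x3/2 max pool, then
# stages of basic (2-conv) blocks [3, 4, 6, 3] at channels [64, 128, 256, 512].
gb_encoder_resnet34 <- function(g) {
  gb_add(g, "input", "input", character(), out_ch = 3L)
  stem <- gb_cbr(g, "stem", "input", 3L, 64L, 7L, 2L)
  pool <- gb_add(g, "stem.pool", "maxpool", stem, 64L, 64L)
  stages <- list(c(3L, 64L), c(4L, 128L), c(6L, 256L), c(3L, 512L))
  x <- pool
  in_ch <- 64L
  enc <- list(list(id = stem, ch = 64L))
  for (s in seq_along(stages)) {
    nblocks <- stages[[s]][1L]; out_ch <- stages[[s]][2L]
    for (b in seq_len(nblocks)) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      x <- gb_res_block(g, sprintf("layer%d.b%d", s, b), x, in_ch, out_ch,
                        stride, 2L)
      in_ch <- out_ch
    }
    enc[[s + 1L]] <- list(id = x, ch = out_ch)
  }
  enc
}

# Iterative deep aggregation decoder: each aggregation node fuses the
# same-level encoder map, the upsampled previous aggregation output, and the
# upsampled deeper encoder map by channel-aligned summation followed by one
# convolution.
gb_decoder_ida <- function(g, enc) {
  L <- length(enc)
  agg <- enc[[L]]
  for (d in rev(seq_len(L - 1L))) {
    ch <- enc[[d]]$ch
    ua <- gb_add(g, sprintf("agg%d.up_agg", d), "upsample", agg$id, agg$ch, agg$ch)
    ua <- gb_align(g, sprintf("agg%d.align_agg", d), ua, agg$ch, ch)
    ue <- gb_add(g, sprintf("agg%d.up_enc", d), "upsample", enc[[d + 1L]]$id,
                 enc[[d + 1L]]$ch, enc[[d + 1L]]$ch)
    ue <- gb_align(g, sprintf("agg%d.align_enc", d), ue, enc[[d + 1L]]$ch, ch)
    s <- gb_add(g, sprintf("agg%d.sum", d), "add", c(enc[[d]]$id, ua, ue), ch, ch)
    f <- gb_cbr(g, sprintf("agg%d.fuse", d), s, ch, ch, 3L, 1L)
    agg <- list(id = f, ch = ch)
  }
  agg
}

# Plain U-Net decoder: upsample, concatenate the same-level encoder map,
# then two conv/bn/relu stages.
gb_decoder_plain <- function(g, enc) {
  L <- length(enc)
  cur <- enc[[L]]
  for (d in rev(seq_len(L - 1L))) {
    ch <- enc[[d]]$ch
    up <- gb_add(g, sprintf("dec%d.up", d), "upsample", cur$id, cur$ch, cur$ch)
    up <- gb_align(g, sprintf("dec%d.align", d), up, cur$ch, ch)
    cat_ <- gb_add(g, sprintf("dec%d.cat", d), "concat",
                   c(up, enc[[d]]$id), 2L * ch, 2L * ch)
    x <- gb_cbr(g, sprintf("dec%d.c1", d), cat_, 2L * ch, ch, 3L, 1L)
    x <- gb_cbr(g, sprintf("dec%d.c2", d), x, ch, ch, 3L, 1L)
    cur <- list(id = x, ch = ch)
  }
  cur
}

build_graph <- function(spec) {
  g <- gb_new()
  enc <- if (spec$backbone == "resnet34") gb_encoder_resnet34(g)
         else gb_encoder_custom(g, spec)
  dec <- if (spec$aggregation == "iterative_deep") gb_decoder_ida(g, enc)
         else gb_decoder_plain(g, enc)
  # The resnet34 encoder's finest map is at half resolution; bring the
  # decoder output back to the input size before the head.
  if (spec$backbone == "resnet34") {
    up <- gb_add(g, "head.up", "upsample", dec$id, dec$ch, dec$ch)
    x <- gb_cbr(g, "head.refine", up, dec$ch, 32L, 3L, 1L)
    dec <- list(id = x, ch = 32L)
  }
  logit <- gb_add(g, "head.conv", "conv", dec$id, dec$ch, 1L, 1L, 1L, 0L)
  out <- gb_add(g, "head.sigmoid", "sigmoid", logit, 1L, 1L)
  list(nodes = g$nodes, logit_id = logit, out_id = out)
}

# ---- parameters and forward pass -------------------------------------------

init_params <- function(graph, seed) {
  params <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  withr::with_seed(seed, {
    for (nd in graph$nodes) {
      if (nd$op == "conv") {
        fan_in <- nd$kh * nd$kh * nd$in_ch
        w <- array(rnorm(nd$kh * nd$kh * nd$in_ch * nd$out_ch, sd = sqrt(2 / fan_in)),
                   c(nd$kh, nd$kh, nd$in_ch, nd$out_ch))
        params[[paste0(nd$id, ".w")]] <- ag_param(w, paste0(nd$id, ".w"))
        params[[paste0(nd$id, ".b")]] <- ag_param(numeric(nd$out_ch), paste0(nd$id, ".b"))
      } else if (nd$op == "bn") {
        params[[paste0(nd$id, ".gamma")]] <- ag_param(rep(1, nd$out_ch), paste0(nd$id, ".gamma"))
        params[[paste0(nd$id, ".beta")]] <- ag_param(numeric(nd$out_ch), paste0(nd$id, ".beta"))
        st <- new.env(parent = emptyenv())
        st$mean <- numeric(nd$out_ch)
        st$var <- rep(1, nd$out_ch)
        state[[nd$id]] <- st
      }
    }
  })
  list(params = params, state = state)
}

#' Build the segmentation model
#'
#' Instantiates the network described by a [residual_unet_spec()]: builds the
#' operation graph and randomly initialises all weights (He initialisation,
#' reproducible via `seed`). The model maps an
#' `input_side x input_side x input_channels` image to an
#' `input_side x input_side` map of foreground probabilities in (0, 1).
#'
#' @param spec A [residual_unet_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `hs_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  if (!inherits(spec, "residual_unet_spec"))
    hs_config_error("spec must be a residual_unet_spec")
  graph <- build_graph(spec)
  ps <- init_params(graph, seed)
  structure(list(spec = spec, graph = graph, params = ps$params,
                 state = ps$state, seed = as.integer(seed)),
            class = "hs_model")
}

#' @export
print.hs_model <- function(x, ...) {
  cat(sprintf(
    "<hs_model> %s backbone, %s aggregation, side %d, %d levels [%s], %s parameters\n",
    x$spec$backbone, x$spec$aggregation, x$spec$input_side, x$spec$n_levels,
    paste(x$spec$channel_schedule, collapse = ","),
    format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model An `hs_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(ls(model$params), function(n) length(model$params[[n]]$value), 0))
}

# Forward interpretation of the graph. x is (H, W, C, N). Returns the output
# and logit nodes plus the tape for backprop.
model_forward <- function(model, x, training = FALSE) {
  tape <- ag_tape()
  out <- list()
  P <- model$params
  for (nd in model$graph$nodes) {
    out[[nd$id]] <- switch(nd$op,
      input = ag_input(tape, x),
      conv = ag_conv(tape, out[[nd$inputs[1L]]],
                     P[[paste0(nd$id, ".w")]], P[[paste0(nd$id, ".b")]],
                     nd$stride, nd$pad),
      bn = ag_bn(tape, out[[nd$inputs[1L]]],
                 P[[paste0(nd$id, ".gamma")]], P[[paste0(nd$id, ".beta")]],
                 model$state[[nd$id]], training),
      relu = ag_relu(tape, out[[nd$inputs[1L]]]),
      add = do.call(ag_add, c(list(tape), out[nd$inputs])),
      upsample = ag_upsample2(tape, out[[nd$inputs[1L]]]),
      maxpool = ag_maxpool2(tape, out[[nd$inputs[1L]]]),
      concat = ag_concat(tape, out[[nd$inputs[1L]]], out[[nd$inputs[2L]]]),
      sigmoid = ag_sigmoid(tape, out[[nd$inputs[1L]]]),
      hs_config_error(sprintf("unknown graph op '%s'", nd$op))
    )
  }
  list(tape = tape, prob = out[[model$graph$out_id]],
       logit = out[[model$graph$logit_id]], nodes = out)
}

# Stack a list of 2-D grayscale images into the (H, W, C, N) input tensor,
# replicating to the model's input channel count.
stack_input <- function(images, channels = 3L) {
  d <- dim(images[[1L]])
  x <- array(0, c(d[1L], d[2L], channels, length(images)))
  for (i in seq_along(images)) {
    for (c in seq_len(channels)) x[, , c, i] <- images[[i]]
  }
  x
}

#' Predict foreground probabilities for a batch of slices
#'
#' @param model An `hs_model`.
#' @param images List of 2-D grayscale matrices in `[0, 1]`.
#' @return List of probability matrices in `(0, 1)`.
#' @export
predict_prob <- function(model, images) {
  side <- model$spec$input_side
  for (img in images) {
    d <- dim(img)
    if (is.null(d) || d[1L] != side || d[2L] != side)
      hs_data_error(sprintf("image is %s but the model expects %dx%d",
                            paste(dim(img), collapse = "x"), side, side))
  }
  x <- stack_input(images, model$spec$input_channels)
  fw <- model_forward(model, x, training = FALSE)
  p <- fw$prob$value
  lapply(seq_along(images), function(i) p[, , 1L, i])
}

#' Predict a binary hemorrhage mask for one slice
#'
#' Runs the network in inference mode and thresholds the sigmoid probability
#' map.
#'
#' @param model An `hs_model`.
#' @param image 2-D grayscale matrix matching the model's input side.
#' @param threshold Probability cut for foreground, default 0.5.
#' @return Binary matrix of 0/1 values.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  p <- predict_prob(model, list(image))[[1L]]
  (p >= threshold) * 1
}

#' Fuse feature maps across depths
#'
#' Functional form of one aggregation node: all input maps are resampled
#' (nearest-neighbour) to the finest input's spatial size, aligned to a
#' common channel count by 1x1 convolution, summed, and passed through one
#' 3x3 convolution. Weights are drawn from the He distribution under `seed`
#' unless supplied.
#'
#' @param maps List of feature arrays with dims (H, W, C, N); spatial sizes
#'   must be related by powers of two.
#' @param out_channels Channel count of the fused map; defaults to the
#'   finest input's channels.
#' @param seed Seed for the convolution weights.
#' @return Fused feature array at the finest input's spatial size.
#' @export
aggregate_features <- function(maps, out_channels = NULL, seed = 1L) {
  if (length(maps) < 1L) hs_config_error("aggregate_features needs at least one map")
  sides <- vapply(maps, function(m) dim(m)[1L], 0)
  fine <- max(sides)
  if (any(fine %% sides != 0) ||
      any(log2(fine / sides) %% 1 != 0))
    hs_config_error("map sizes must be related by powers of two")
  if (is.null(out_channels)) out_channels <- dim(maps[[which.max(sides)]])[3L]
  withr::with_seed(seed, {
    aligned <- lapply(maps, function(m) {
      while (dim(m)[1L] < fine) {
        ri <- rep(seq_len(dim(m)[1L]), each = 2L)
        ci <- rep(seq_len(dim(m)[2L]), each = 2L)
        m <- m[ri, ci, , , drop = FALSE]
      }
      cin <- dim(m)[3L]
      w <- array(rnorm(cin * out_channels, sd = sqrt(2 / cin)),
                 c(1L, 1L, cin, out_channels))
      conv2d_fwd_cpp(m, w, numeric(out_channels), 1L, 0L)
    })
    s <- Reduce(`+`, aligned)
    wf <- array(rnorm(9 * out_channels * out_channels, sd = sqrt(2 / (9 * out_channels))),
                c(3L, 3L, out_channels, out_channels))
    conv2d_fwd_cpp(s, wf, numeric(out_channels), 1L, 1L)
  })
}

#' Export the model's layer graph
#'
#' @param model An `hs_model`.
#' @param path Optional file to write JSON to.
#' @return Data frame of graph nodes (one row per op), invisibly if written.
#' @export
model_graph <- function(model, path = NULL) {
  df <- do.call(rbind, lapply(model$graph$nodes, function(nd) {
    data.frame(id = nd$id, op = nd$op,
               inputs = paste(nd$inputs, collapse = ","),
               in_ch = nd$in_ch, out_ch = nd$out_ch, kh = nd$kh,
               stride = nd$stride, pad = nd$pad,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  if (!is.null(path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
    return(invisible(df))
  }
  df
}
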