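# Staining-invariant encoder (SIE): five stages S0-S4, each halving the
# spatial side. S0 is a convolutional stem (two 3x3 convolutions, the first
# with stride 2) closed by a WHDC block; S1 is an MBConv stage closed by a
# second WHDC block; S2 is an MBConv stage without WHDC; S3 and S4 are
# transformer stages (stride-2 max-pool entry, then pre-norm multi-head
# self-attention with a learned 2D relative position bias and an FFN).

#' Encoder configuration
#'
#' The `full` preset follows the CoAtNet-0 scale (channels
#' 64/96/192/384/768, depths 2/2/3/5/2, 8 heads); the `tiny` preset
#' (16/24/32/64/128, depth 1 everywhere, 2 heads) is sized for CPU work and
#' tests. For a 256 input the stage sides are 128/64/32/16/8, so the S4
#' bottleneck map is 8x8.
#'
#' @param preset `"tiny"` or `"full"`.
#' @param input_size Input side in pixels; must be divisible by 32.
#' @param stage_channels,stage_depths,attention_heads Optional overrides of
#'   the preset values (5 channel counts, 5 depths, a head count).
#' @param whdc Optional [whdc_config()] template; its `channels` field is
#'   set per stage.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(preset = c("tiny", "full"), input_size = 256L,
                           stage_channels = NULL, stage_depths = NULL,
                           attention_heads = NULL, whdc = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    full = list(channels = c(64L, 96L, 192L, 384L, 768L),
                depths = c(2L, 2L, 3L, 5L, 2L), heads = 8L),
    tiny = list(channels = c(16L, 24L, 32L, 64L, 128L),
                depths = c(1L, 1L, 1L, 1L, 1L), heads = 2L)
  )
  stage_channels <- as.integer(stage_channels %||% defaults$channels)
  stage_depths <- as.integer(stage_depths %||% defaults$depths)
  attention_heads <- as.integer(attention_heads %||% defaults$heads)
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  if (length(stage_channels) != 5L || length(stage_depths) != 5L) {
    stop("stage_channels and stage_depths must have length 5")
  }
  if (any(diff(stage_channels) < 0)) stop("stage_channels must be nondecreasing")
  structure(list(preset = preset, input_size = input_size,
                 stage_channels = stage_channels, stage_depths = stage_depths,
                 attention_heads = attention_heads,
                 whdc = whdc %||% whdc_config(stage_channels[1])),
            class = "encoder_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_side <- function(input_size, k) as.integer(input_size / 2^(k + 1))

whdc_cfg_for <- function(cfg, channels) {
  whdc_config(channels, cfg$whdc$dilation_rates, cfg$whdc$kernel,
              cfg$whdc$reduction_ratio)
}

#' Initialize encoder parameters
#'
#' @param cfg An [encoder_config()].
#' @param seed Integer seed (or an [rng_stream()]).
#' @return Nested parameter list covering stages S0-S4.
#' @export
encoder_init <- function(cfg, seed = 1L) {
  rng <- if (inherits(seed, "rng_stream")) seed else rng_stream(seed)
  ch <- cfg$stage_channels
  p <- list()
  p$s0 <- list(
    conv1 = conv_bn_new(rng, 3L, 3L, ch[1]),
    conv2 = conv_bn_new(rng, 3L, ch[1], ch[1]),
    whdc = whdc_init(whdc_cfg_for(cfg, ch[1]), rng)
  )
  p$s1 <- list(
    blocks = mbconv_stack(rng, ch[1], ch[2], cfg$stage_depths[2]),
    whdc = whdc_init(whdc_cfg_for(cfg, ch[2]), rng)
  )
  p$s2 <- list(blocks = mbconv_stack(rng, ch[2], ch[3], cfg$stage_depths[3]))
  s3_side <- stage_side(cfg$input_size, 3L)
  s4_side <- stage_side(cfg$input_size, 4L)
  p$s3 <- transformer_stage_new(rng, ch[3], ch[4], cfg$stage_depths[4],
                                cfg$attention_heads, s3_side)
  p$s4 <- transformer_stage_new(rng, ch[4], ch[5], cfg$stage_depths[5],
                                cfg$attention_heads, s4_side)
  p
}

mbconv_stack <- function(rng, cin, cout, depth) {
  lapply(seq_len(depth), function(i) {
    if (i == 1L) mbconv_new(rng, cin, cout, stride = 2L)
    else mbconv_new(rng, cout, cout, stride = 1L)
  })
}

transformer_stage_new <- function(rng, cin, cout, depth, heads, side) {
  list(
    proj = list(w = init_conv_w(rng, 1L, cin, cout), b = rep(0, cout)),
    blocks = lapply(seq_len(depth), function(i) {
      transformer_block_new(rng, cout, heads, side, side)
    })
  )
}

# Tape-level stage forwards ------------------------------------------------

nn_conv_stem <- function(g, x, cfg, p, training = FALSE) {
  h <- nn_conv_bn_gelu(g, x, p$conv1, stride = 2L, pad = 1L, training = training)
  h <- nn_conv_bn_gelu(g, h, p$conv2, stride = 1L, pad = 1L, training = training)
  nn_whdc(g, h, whdc_cfg_for(cfg, cfg$stage_channels[1]), p$whdc, training)
}

nn_mbconv_stage <- function(g, x, cfg, p, stage_index, training = FALSE,
                            use_whdc = stage_index == 1L) {
  h <- x
  for (blk in p$blocks) h <- nn_mbconv(g, h, blk, training)
  if (stage_index == 1L && use_whdc) {
    h <- nn_whdc(g, h, whdc_cfg_for(cfg, cfg$stage_channels[2]), p$whdc, training)
  }
  h
}

nn_transformer_stage <- function(g, x, p, training = FALSE) {
  h <- ad_maxpool(g, x, 2L, 2L)
  h <- ad_conv2d(g, h, p$proj$w, p$proj$b, stride = 1L, pad = 0L)
  d <- dim(h$value)
  tok <- ad_reshape(g, h, c(d[1] * d[2], d[3]))
  for (blk in p$blocks) tok <- nn_transformer_block(g, tok, blk)
  ad_reshape(g, tok, d)
}

nn_encode <- function(g, x, cfg, p, training = FALSE, use_whdc_s1 = TRUE) {
  s0 <- nn_conv_stem(g, x, cfg, p$s0, training)
  s1 <- nn_mbconv_stage(g, s0, cfg, p$s1, 1L, training, use_whdc = use_whdc_s1)
  s2 <- nn_mbconv_stage(g, s1, cfg, p$s2, 2L, training)
  s3 <- nn_transformer_stage(g, s2, p$s3, training)
  s4 <- nn_transformer_stage(g, s3, p$s4, training)
  list(s0 = s0, s1 = s1, s2 = s2, s3 = s3, s4 = s4,
       bottleneck = ad_gap(g, s4))
}

# Array-level public surface ----------------------------------------------

check_encoder_input <- function(x, cfg) {
  if (!(is.numeric(x) && length(dim(x)) == 3L && dim(x)[3] == 3L)) {
    stop("expected an H x W x 3 image array")
  }
  if (dim(x)[1] != cfg$input_size || dim(x)[2] != cfg$input_size) {
    stop("input is ", dim(x)[1], "x", dim(x)[2], " but the encoder expects ",
         cfg$input_size, "x", cfg$input_size)
  }
  invisible(x)
}

#' Convolutional stem (stage S0)
#'
#' Two 3x3 convolutions (the first with stride 2), each with batch
#' normalization and GELU, closed by a WHDC block; halves the spatial side.
#'
#' @param x Image array `H x W x 3` at the configured input size.
#' @param cfg An [encoder_config()].
#' @param params Encoder parameters ([encoder_init()]).
#' @param training Batch statistics vs running estimates.
#' @return Feature map array.
#' @export
conv_stem <- function(x, cfg, params, training = FALSE) {
  check_encoder_input(x, cfg)
  g <- ad_graph()
  pn <- wrap_params(g, params$s0, trainable = FALSE)
  nn_conv_stem(g, ad_const(g, x), cfg, pn, training)$value
}

#' MBConv stage (S1 or S2)
#'
#' Inverted-residual blocks (1x1 expand, 3x3 depthwise, squeeze-excitation,
#' 1x1 project), first block with stride 2. Stage 1 is closed by a WHDC
#' block; stage 2 is identical but without WHDC.
#'
#' @param x Feature map from the previous stage.
#' @param stage_index 1 or 2.
#' @inheritParams conv_stem
#' @return Feature map array with half the spatial side of `x`.
#' @export
mbconv_stage <- function(x, stage_index, cfg, params, training = FALSE) {
  stopifnot(stage_index %in% c(1L, 2L))
  check_feature_map(x)
  key <- paste0("s", stage_index)
  g <- ad_graph()
  pn <- wrap_params(g, params[[key]], trainable = FALSE)
  nn_mbconv_stage(g, ad_const(g, x), cfg, pn, as.integer(stage_index),
                  training)$value
}

#' Transformer stage (S3 or S4)
#'
#' Stride-2 max-pool entry with a 1x1 channel projection, then pre-norm
#' transformer blocks (multi-head self-attention with 2D relative position
#' bias, FFN, residuals).
#'
#' @param x Feature map from the previous stage.
#' @param stage_index 3 or 4.
#' @inheritParams conv_stem
#' @return Feature map array with half the spatial side of `x`.
#' @export
transformer_stage <- function(x, stage_index, cfg, params, training = FALSE) {
  stopifnot(stage_index %in% c(3L, 4L))
  check_feature_map(x)
  key <- paste0("s", stage_index)
  g <- ad_graph()
  pn <- wrap_params(g, params[[key]], trainable = FALSE)
  nn_transformer_stage(g, ad_const(g, x), pn, training)$value
}

#' Encode an image through all five stages
#'
#' @param x Image array `H x W x 3` in `[0, 1]` at the configured input size.
#' @param cfg An [encoder_config()].
#' @param params Encoder parameters ([encoder_init()]).
#' @param training Batch statistics vs running estimates.
#' @return A `stage_outputs` list: feature maps `s0`-`s4` plus `bottleneck`,
#'   the global average pool of `s4` (length `stage_channels[5]`).
#' @export
encode <- function(x, cfg, params, training = FALSE) {
  check_encoder_input(x, cfg)
  g <- ad_graph()
  pn <- wrap_params(g, params, trainable = FALSE)
  out <- nn_encode(g, ad_const(g, x), cfg, pn, training)
  structure(lapply(out, function(nd) nd$value), class = "stage_outputs")
}

#' Write per-stage feature-map heatmaps
#'
#' For each stage, the channel-mean map is min-max normalized and written
#' as an 8-bit grayscale PNG, for qualitative inspection of what the
#' encoder responds to.
#'
#' @param stages A `stage_outputs` object from [encode()].
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return Invisibly, the written paths.
#' @export
dump_stage_heatmaps <- function(stages, dir, prefix = "stage") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("s0", "s1", "s2", "s3", "s4")) {
    m <- apply(stages[[nm]], c(1, 2), mean)
    rg <- range(m)
    m <- if (diff(rg) > 0) (m - rg[1]) / diff(rg) else m * 0
    path <- file.path(dir, paste0(prefix, "_", nm, ".png"))
    png::writePNG(m, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
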