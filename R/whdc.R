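# Weighted hybrid dilated convolution (WHDC): four cascaded 3x3 dilated
# convolutions (rates 3, 6, 9, 18 by default), each conv -> batch-norm ->
# GELU, with a sigmoid self-weighting gate per branch and a channel
# attention mechanism over the concatenation of the gated branches and the
# block input. A final 1x1 projection restores the input channel count, so
# the block preserves C, H and W and can close encoder stages S0 and S1.

#' WHDC block configuration
#'
#' @param channels Number of input (= output) channels.
#' @param dilation_rates Strictly increasing positive dilation rates, one per
#'   cascaded branch.
#' @param kernel Convolution kernel size (square).
#' @param reduction_ratio Channel reduction ratio of the channel attention
#'   bottleneck.
#' @return A `whdc_config` list.
#' @export
whdc_config <- function(channels, dilation_rates = c(3L, 6L, 9L, 18L),
                        kernel = 3L, reduction_ratio = 16L) {
  if (any(dilation_rates <= 0) || any(diff(dilation_rates) <= 0)) {
    stop("dilation_rates must be strictly increasing and positive")
  }
  if (channels < 1) stop("channels must be >= 1")
  structure(list(channels = as.integer(channels),
                 dilation_rates = as.integer(dilation_rates),
                 kernel = as.integer(kernel),
                 reduction_ratio = as.integer(reduction_ratio)),
            class = "whdc_config")
}

cam_new <- function(rng, c, reduction_ratio) {
  hidden <- max(1L, as.integer(round(c / reduction_ratio)))
  list(w1 = init_linear_w(rng, c, hidden), b1 = rep(0, hidden),
       w2 = init_linear_w(rng, hidden, c), b2 = rep(0, c))
}

#' Initialize WHDC parameters
#'
#' @param cfg A [whdc_config()].
#' @param rng An [rng_stream()] (or an integer seed).
#' @return Nested parameter list (branch convolutions, gates, channel
#'   attention, output projection).
#' @export
whdc_init <- function(cfg, rng) {
  if (!inherits(rng, "rng_stream")) rng <- rng_stream(rng)
  C <- cfg$channels
  k <- cfg$kernel
  nb <- length(cfg$dilation_rates)
  branches <- lapply(seq_len(nb), function(i) conv_bn_new(rng, k, C, C))
  gates <- lapply(seq_len(nb), function(i) {
    list(a = init_linear_w(rng, C, 1L), b = 0)
  })
  ccat <- (nb + 1L) * C
  list(branches = branches, gates = gates,
       cam = cam_new(rng, ccat, cfg$reduction_ratio),
       proj = list(w = init_conv_w(rng, 1L, ccat, C), b = rep(0, C)))
}

# Tape-level forward pieces -----------------------------------------------

nn_dilated_branch <- function(g, x, p, rate, kernel, training) {
  # padding = rate keeps H x W for kernel 3
  pad <- as.integer(rate * (kernel - 1L) / 2L)
  nn_conv_bn_gelu(g, x, p, stride = 1L, pad = pad, dilation = rate,
                  training = training)
}

nn_branch_gate <- function(g, branch_out, p) {
  s <- ad_gap(g, branch_out)
  s <- ad_reshape(g, s, c(1L, length(s$value)))
  z <- ad_add(g, ad_matmul(g, s, p$a), p$b)
  z <- ad_reshape(g, z, 1L)
  ad_sigmoid(g, z)
}

nn_channel_attention <- function(g, x, p) {
  s <- ad_gap(g, x)
  s <- ad_reshape(g, s, c(1L, length(s$value)))
  h <- ad_relu(g, ad_add_col_bias(g, ad_matmul(g, s, p$w1), p$b1))
  sc <- ad_sigmoid(g, ad_add_col_bias(g, ad_matmul(g, h, p$w2), p$b2))
  sc <- ad_reshape(g, sc, length(sc$value))
  ad_scale_channels(g, x, sc)
}

nn_whdc <- function(g, x, cfg, p, training = FALSE) {
  if (dim(x$value)[3] != cfg$channels) {
    stop("whdc: input has ", dim(x$value)[3], " channels, config expects ",
         cfg$channels)
  }
  prev <- x
  weighted <- vector("list", length(cfg$dilation_rates))
  for (i in seq_along(cfg$dilation_rates)) {
    br <- nn_dilated_branch(g, prev, p$branches[[i]], cfg$dilation_rates[i],
                            cfg$kernel, training)
    gate <- nn_branch_gate(g, br, p$gates[[i]])
    weighted[[i]] <- ad_mul(g, br, gate)
    prev <- br
  }
  cat5 <- ad_concat_c(g, c(weighted, list(x)))
  att <- nn_channel_attention(g, cat5, p$cam)
  ad_conv2d(g, att, p$proj$w, p$proj$b, stride = 1L, pad = 0L)
}

# Array-level public surface ----------------------------------------------

#' One dilated convolution branch (conv -> batch-norm -> GELU)
#'
#' Shape preserving: padding equals the dilation rate for a 3x3 kernel.
#'
#' @param x Feature map, array `H x W x C`.
#' @param rate Dilation rate.
#' @param params Branch parameters (one element of `whdc_init()$branches`).
#' @param kernel Kernel size.
#' @param training Use batch statistics (`TRUE`) or running estimates.
#' @return Array of the same dimensions as `x`.
#' @export
dilated_branch <- function(x, rate, params, kernel = 3L, training = FALSE) {
  check_feature_map(x)
  if (dim(x)[3] != dim(params$w)[3]) {
    stop("dilated_branch: channel mismatch (input ", dim(x)[3],
         ", weight ", dim(params$w)[3], ")")
  }
  g <- ad_graph()
  pn <- wrap_params(g, params, trainable = FALSE)
  nn_dilated_branch(g, ad_const(g, x), pn, rate, as.integer(kernel),
                    training)$value
}

#' Sigmoid self-weighting gate of a WHDC branch
#'
#' The gate is `sigmoid(a' gap(x) + b)`: a learned linear read-out of the
#' branch's globally pooled features, squashed to (0, 1).
#'
#' @param branch_out Branch output, array `H x W x C`.
#' @param params Gate parameters: list with `a` (C x 1) and scalar `b`.
#' @return A scalar strictly inside (0, 1).
#' @export
branch_gate <- function(branch_out, params) {
  check_feature_map(branch_out)
  g <- ad_graph()
  pn <- wrap_params(g, params, trainable = FALSE)
  nn_branch_gate(g, ad_const(g, branch_out), pn)$value
}

#' Channel attention (squeeze-and-excitation over concatenated maps)
#'
#' Global average pool per channel, a two-layer bottleneck
#' (`C -> C/r -> C`) with ReLU then sigmoid, and per-channel rescaling of
#' the input.
#'
#' @param x Feature map, array `H x W x C`.
#' @param params Parameters from `cam_init()` / `whdc_init()$cam`.
#' @param reduction_ratio Reduction ratio used to validate `C`.
#' @return Array of the same dimensions as `x`.
#' @export
channel_attention <- function(x, params, reduction_ratio = 16L) {
  check_feature_map(x)
  if (dim(x)[3] < reduction_ratio) {
    stop("channel_attention: C (", dim(x)[3], ") must be >= reduction_ratio (",
         reduction_ratio, ")")
  }
  g <- ad_graph()
  pn <- wrap_params(g, params, trainable = FALSE)
  nn_channel_attention(g, ad_const(g, x), pn)$value
}

#' Initialize channel attention parameters
#'
#' @param channels Number of channels.
#' @param reduction_ratio Bottleneck reduction ratio.
#' @param rng An [rng_stream()] or integer seed.
#' @return Parameter list (`w1`, `b1`, `w2`, `b2`).
#' @export
cam_init <- function(channels, reduction_ratio = 16L, rng = 1L) {
  if (!inherits(rng, "rng_stream")) rng <- rng_stream(rng)
  cam_new(rng, as.integer(channels), reduction_ratio)
}

#' Forward pass of the WHDC block
#'
#' @param x Feature map, array `H x W x C` with `C == cfg$channels`.
#' @param cfg A [whdc_config()].
#' @param params Parameters from [whdc_init()].
#' @param training Use batch statistics (`TRUE`) or running estimates.
#' @return Array of the same dimensions as `x`.
#' @export
whdc_forward <- function(x, cfg, params, training = FALSE) {
  check_feature_map(x)
  g <- ad_graph()
  pn <- wrap_params(g, params, trainable = FALSE)
  nn_whdc(g, ad_const(g, x), cfg, pn, training)$value
}

check_feature_map <- function(x) {
  if (!(is.numeric(x) && length(dim(x)) == 3L)) {
    stop("expected a numeric H x W x C array")
  }
  if (any(!is.finite(x))) stop("feature map contains non-finite values")
  invisible(x)
}
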