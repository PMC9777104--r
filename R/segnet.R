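# Downstream nuclei segmentation network: the (optionally pretrained)
# encoder, a five-layer transposed-convolution decoder with additive
# attention gates on the four skip connections, the combined BCE + Dice
# training loss, and thresholded inference.

#' Segmentation training configuration
#'
#' Defaults follow the published recipe: Adam with beta1 = 0.5,
#' beta2 = 0.999, learning rate 2e-4, 100 epochs, mini-batch 4, loss
#' weight gamma = 0.4, threshold 0.5.
#'
#' @param decoder_channels Optional 5 output widths for the decoder layers;
#'   by default they mirror the encoder stage widths (last layer emits 1
#'   channel).
#' @param threshold Probability threshold for binarization, in (0, 1).
#' @param gamma BCE weight in the combined loss, in `[0, 1]`.
#' @param lr,betas Adam learning rate and moment decays.
#' @param epochs,batch_size Training schedule.
#' @param freeze_encoder Keep encoder weights fixed during segmentation
#'   training (by default the encoder is fine-tuned).
#' @param augment Apply aligned geometric augmentation (flips, 90-degree
#'   rotations) to image/mask pairs during training.
#' @param seed Integer run seed.
#' @return A `seg_config` list.
#' @export
seg_config <- function(decoder_channels = NULL, threshold = 0.5, gamma = 0.4,
                       lr = 2e-4, betas = c(0.5, 0.999), epochs = 100L,
                       batch_size = 4L, freeze_encoder = FALSE,
                       augment = TRUE, seed = 1L) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(decoder_channels = decoder_channels, threshold = threshold,
                 gamma = gamma, lr = lr, betas = betas,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 freeze_encoder = isTRUE(freeze_encoder),
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "seg_config")
}

default_decoder_channels <- function(enc_channels) {
  c(enc_channels[4], enc_channels[3], enc_channels[2], enc_channels[1], 1L)
}

ag_new <- function(rng, c_skip, c_gate) {
  fint <- max(1L, c_skip %/% 2L)
  list(wx = init_linear_w(rng, c_skip, fint),
       wg = init_linear_w(rng, c_gate, fint),
       b = rep(0, fint),
       psi = init_linear_w(rng, fint, 1L),
       bpsi = 0)
}

decoder_init <- function(enc_cfg, cfg, rng) {
  ch <- enc_cfg$stage_channels
  dch <- as.integer(cfg$decoder_channels %||% default_decoder_channels(ch))
  if (length(dch) != 5L) stop("decoder_channels must have length 5")
  cin <- c(ch[5], dch[1] + ch[4], dch[2] + ch[3], dch[3] + ch[2], dch[4] + ch[1])
  layers <- lapply(seq_len(5L), function(k) {
    p <- list(w = init_convT_w(rng, 4L, dch[k], cin[k]), b = rep(0, dch[k]))
    if (k < 5L) p$bn <- bn_new(dch[k])
    p
  })
  # gate k rescales the skip from stage s_{4-k}; the gating signal is the
  # decoder state before the k-th upsampling
  skips <- c(ch[4], ch[3], ch[2], ch[1])
  gates <- lapply(seq_len(4L), function(k) ag_new(rng, skips[k], cin[k]))
  list(layers = layers, ag = gates)
}

nn_attention_gate <- function(g, skip, gating, p) {
  ds <- dim(skip$value)
  dg <- dim(gating$value)
  if (ds[1] == 2L * dg[1] && ds[2] == 2L * dg[2]) {
    gating <- ad_upsample2(g, gating)
  } else if (!(ds[1] == dg[1] && ds[2] == dg[2])) {
    stop("attention gate: gating map must match the skip size or be half of it")
  }
  st <- ad_reshape(g, skip, c(ds[1] * ds[2], ds[3]))
  gt <- ad_reshape(g, gating, c(ds[1] * ds[2], dg[3]))
  q <- ad_add_col_bias(g, ad_add(g, ad_matmul(g, st, p$wx),
                                 ad_matmul(g, gt, p$wg)), p$b)
  coeff <- ad_sigmoid(g, ad_add(g, ad_matmul(g, ad_relu(g, q), p$psi), p$bpsi))
  coeff <- ad_reshape(g, coeff, ds[1] * ds[2])
  gated <- ad_scale_rows(g, st, coeff)
  ad_reshape(g, gated, ds)
}

nn_decode <- function(g, stages, dp, training = FALSE) {
  x <- stages$s4
  skips <- list(stages$s3, stages$s2, stages$s1, stages$s0)
  for (k in 1:4) {
    p <- dp$layers[[k]]
    u <- ad_conv2d_transpose(g, x, p$w, p$b)
    u <- ad_batchnorm(g, u, p$bn$gamma, p$bn$beta, p$bn$rstate, training)
    u <- ad_relu(g, u)
    gated <- nn_attention_gate(g, skips[[k]], x, dp$ag[[k]])
    x <- ad_concat_c(g, list(u, gated))
  }
  p5 <- dp$layers[[5]]
  out <- ad_sigmoid(g, ad_conv2d_transpose(g, x, p5$w, p5$b))
  d <- dim(out$value)
  ad_reshape(g, out, d[1:2])
}

#' Additive attention gate over a skip connection
#'
#' 1x1 maps on the skip and the (upsampled) gating signal are summed,
#' passed through ReLU, a 1x1 map and a sigmoid, giving a coefficient map
#' in (0, 1) that rescales the skip features pixel-wise.
#'
#' @param skip Skip feature map, `H x W x Cs`.
#' @param gating Gating feature map at the same or half the spatial size.
#' @param params Gate parameters (`wx`, `wg`, `b`, `psi`, `bpsi`).
#' @return Array shaped like `skip`.
#' @export
attention_gate <- function(skip, gating, params) {
  check_feature_map(skip); check_feature_map(gating)
  g <- ad_graph()
  pn <- wrap_params(g, params, trainable = FALSE)
  nn_attention_gate(g, ad_const(g, skip), ad_const(g, gating), pn)$value
}

#' Initialize attention gate parameters
#'
#' @param c_skip,c_gate Channel counts of the skip and gating maps.
#' @param rng An [rng_stream()] or integer seed.
#' @return Parameter list.
#' @export
attention_gate_init <- function(c_skip, c_gate, rng = 1L) {
  if (!inherits(rng, "rng_stream")) rng <- rng_stream(rng)
  ag_new(rng, as.integer(c_skip), as.integer(c_gate))
}

#' Decode stage outputs into a nucleus probability map
#'
#' Five 4x4 stride-2 transposed convolutions double the resolution at each
#' step (8 to 256 for a 256 input); layers 1-4 use batch-norm + ReLU and
#' concatenate the attention-gated skip from stages s3..s0; the final layer
#' maps to one channel through a sigmoid.
#'
#' @param stages A `stage_outputs` object from [encode()].
#' @param decoder_params Decoder parameter tree (from a trained model).
#' @param training Batch statistics vs running estimates.
#' @return `H x W` matrix of probabilities strictly inside (0, 1).
#' @export
decode <- function(stages, decoder_params, training = FALSE) {
  g <- ad_graph()
  pn <- wrap_params(g, decoder_params, trainable = FALSE)
  snodes <- lapply(stages[c("s0", "s1", "s2", "s3", "s4")],
                   function(a) ad_const(g, a))
  nn_decode(g, snodes, pn, training)$value
}

# ---- losses -------------------------------------------------------------

check_same_shape <- function(y, t) {
  if (!all(dim_or_len(y) == dim_or_len(t))) {
    stop("mask and prediction shapes differ")
  }
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-(y log t + (1 - y) log(1 - t))`, with `t` clamped
#' to `[1e-7, 1 - 1e-7]`.
#'
#' @param y Binary ground-truth mask.
#' @param t Predicted probabilities, same shape.
#' @param eps Clamping constant.
#' @return Nonnegative scalar.
#' @export
bce_loss <- function(y, t, eps = 1e-7) {
  check_same_shape(y, t)
  tc <- pmin(pmax(t, eps), 1 - eps)
  mean(-(y * log(tc) + (1 - y) * log(1 - tc)))
}

#' Dice loss
#'
#' `1 - (2 sum(y t) + s) / (sum(y^2) + sum(t^2) + s)` with smoothing
#' `s = 1e-6`, so two empty masks score a perfect 0.
#'
#' @inheritParams bce_loss
#' @param smooth Smoothing constant.
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(y, t, smooth = 1e-6) {
  check_same_shape(y, t)
  1 - (2 * sum(y * t) + smooth) / (sum(y^2) + sum(t^2) + smooth)
}

#' Combined segmentation loss
#'
#' `gamma * BCE + (1 - gamma) * Dice`, the convex combination used for
#' training (gamma = 0.4 by default).
#'
#' @inheritParams bce_loss
#' @param gamma BCE weight in `[0, 1]`.
#' @return Nonnegative scalar.
#' @export
combined_loss <- function(y, t, gamma = 0.4) {
  stopifnot(gamma >= 0, gamma <= 1)
  gamma * bce_loss(y, t) + (1 - gamma) * dice_loss(y, t)
}

nn_bce <- function(g, y, t, eps = 1e-7) {
  tc <- ad_clamp(g, t, eps, 1 - eps)
  yv <- y$value
  term <- ad_add(g, ad_mul(g, ad_const(g, yv), ad_log(g, tc)),
                 ad_mul(g, ad_const(g, 1 - yv),
                        ad_log(g, ad_sub(g, ad_const(g, array(1, dim_or_len(yv))), tc))))
  ad_neg(g, ad_mean(g, term))
}

nn_dice <- function(g, y, t, smooth = 1e-6) {
  yv <- y$value
  inter <- ad_sum(g, ad_mul(g, ad_const(g, yv), t))
  ssum <- ad_add(g, ad_const(g, sum(yv^2)), ad_sum(g, ad_mul(g, t, t)))
  frac <- ad_div(g, ad_add(g, ad_scale_const(g, inter, 2), ad_const(g, smooth)),
                 ad_add(g, ssum, ad_const(g, smooth)))
  ad_sub(g, ad_const(g, 1), frac)
}

nn_combined <- function(g, y, t, gamma) {
  ad_add(g, ad_scale_const(g, nn_bce(g, y, t), gamma),
         ad_scale_const(g, nn_dice(g, y, t), 1 - gamma))
}

# ---- training -----------------------------------------------------------

# Accept a patch_set, a manifest data frame / CSV path with image and mask
# columns, or an in-memory list of list(image=, mask=) pairs.
collect_pairs <- function(patchset, input_size) {
  pairs <- if (inherits(patchset, "patch_set")) {
    lapply(seq_len(nrow(patchset$index)), function(i) read_crop(patchset, i))
  } else if (is.data.frame(patchset) || is.character(patchset)) {
    man <- read_manifest(patchset)
    lapply(seq_len(nrow(man)), function(i) {
      list(image = load_image(man$image[i]), mask = load_mask(man$mask[i]))
    })
  } else if (is.list(patchset)) {
    patchset
  } else {
    stop("unsupported patchset type")
  }
  lapply(pairs, function(p) {
    img <- p$image
    msk <- p$mask
    if (dim(img)[1] != input_size || dim(img)[2] != input_size) {
      img <- resize_image(img, input_size)
      msk <- resize_mask(msk, input_size)
    }
    list(image = img, mask = (msk > 0) * 1)
  })
}

#' Train the nuclei segmentation network
#'
#' The encoder is initialized from a contrastive checkpoint when one is
#' given and randomly otherwise; both arms share the decoder architecture.
#' Optimizes the combined BCE + Dice loss with Adam, logging the mean
#' training loss per epoch (`train_loss.csv`) and saving a final model
#' checkpoint.
#'
#' @param patchset Training data: a `patch_set`, a manifest data frame or
#'   CSV path (columns `image`, `mask`), or a list of
#'   `list(image =, mask =)` pairs.
#' @param checkpoint Optional pretrained encoder checkpoint (path or loaded
#'   object); its config must match `encoder_cfg` when both are given.
#' @param encoder_cfg An [encoder_config()]; defaults to the checkpoint's.
#' @param cfg A [seg_config()].
#' @param out_dir Output directory.
#' @return List with `checkpoint` (path), `loss_log`, `params`,
#'   `encoder_cfg`, `seg_cfg`.
#' @export
train_segmentation <- function(patchset, checkpoint = NULL, encoder_cfg = NULL,
                               cfg = seg_config(), out_dir = tempfile("segtrain")) {
  ck <- NULL
  if (!is.null(checkpoint)) {
    ck <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
    if (!is.null(encoder_cfg)) check_config_compatible(ck$config, encoder_cfg)
    encoder_cfg <- ck$config
  }
  if (is.null(encoder_cfg)) {
    stop("either a pretrained checkpoint or an encoder_cfg is required")
  }
  pairs <- collect_pairs(patchset, encoder_cfg$input_size)
  if (length(pairs) == 0L) stop("patchset is empty")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  init_rng <- rng_stream(derive_seed(cfg$seed, "seg-init"))
  order_rng <- rng_stream(derive_seed(cfg$seed, "seg-order"))
  aug_rng <- rng_stream(derive_seed(cfg$seed, "seg-augment"))
  enc <- if (!is.null(ck)) ck$params else encoder_init(encoder_cfg, init_rng)
  dec <- decoder_init(encoder_cfg, cfg, init_rng)
  params <- list(encoder = enc, decoder = dec)
  opt <- opt_adam(lr = cfg$lr, beta1 = cfg$betas[1], beta2 = cfg$betas[2])
  n <- length(pairs)
  loss_log <- data.frame(epoch = integer(0), mean_loss = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- rng_sample(order_rng, seq_len(n))
    batch_losses <- numeric(0)
    b <- 1L
    while (b <= n) {
      idx <- ord[b:min(b + cfg$batch_size - 1L, n)]
      g <- ad_graph()
      pn <- list(encoder = wrap_params(g, params$encoder, "encoder",
                                       trainable = !cfg$freeze_encoder),
                 decoder = wrap_params(g, params$decoder, "decoder"))
      total <- NULL
      for (ii in idx) {
        pr <- pairs[[ii]]
        img <- pr$image; msk <- pr$mask
        if (cfg$augment) {
          a <- augment_pair_geometric(img, msk, rng = aug_rng)
          img <- a$image; msk <- a$mask
        }
        st <- nn_encode(g, ad_const(g, img), encoder_cfg, pn$encoder,
                        training = TRUE)
        prob <- nn_decode(g, st, pn$decoder, training = TRUE)
        l <- nn_combined(g, ad_const(g, msk), prob, cfg$gamma)
        total <- if (is.null(total)) l else ad_add(g, total, l)
      }
      loss <- ad_scale_const(g, total, 1 / length(idx))
      ad_backward(g, loss)
      params <- apply_gradients(params, ad_grads(g), opt)
      batch_losses <- c(batch_losses, loss$value)
      b <- b + cfg$batch_size
    }
    loss_log <- rbind(loss_log,
                      data.frame(epoch = epoch, mean_loss = mean(batch_losses)))
    utils::write.csv(loss_log, file.path(out_dir, "train_loss.csv"),
                     row.names = FALSE)
  }
  ckpt <- file.path(out_dir, "segmodel.rds")
  save_checkpoint(ckpt, "segmodel", list(encoder = encoder_cfg, seg = cfg),
                  params)
  list(checkpoint = ckpt, loss_log = loss_log, params = params,
       encoder_cfg = encoder_cfg, seg_cfg = cfg)
}

as_seg_model <- function(model) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (!is.null(model$kind) && identical(model$kind, "segmodel")) {
    return(list(params = model$params, encoder_cfg = model$config$encoder,
                seg_cfg = model$config$seg))
  }
  if (!is.null(model$params) && !is.null(model$encoder_cfg)) {
    return(list(params = model$params, encoder_cfg = model$encoder_cfg,
                seg_cfg = model$seg_cfg %||% seg_config()))
  }
  stop("not a segmentation model (expected a train_segmentation() result or checkpoint)")
}

#' Predict a binary nucleus mask
#'
#' Runs the model in inference mode and binarizes with
#' `pixel = 1 iff probability >= threshold`.
#'
#' @param img Image array `H x W x 3` in `[0, 1]` (resized to the model
#'   input size if needed).
#' @param model A [train_segmentation()] result or a segmodel checkpoint
#'   path.
#' @param threshold Probability threshold; defaults to the model's
#'   configured value (0.5).
#' @return `H x W` integer matrix in {0, 1}.
#' @export
predict_mask <- function(img, model, threshold = NULL) {
  m <- as_seg_model(model)
  threshold <- threshold %||% m$seg_cfg$threshold
  prob <- predict_prob(img, model)
  (prob >= threshold) * 1L
}

#' Predict a nucleus probability map
#'
#' @inheritParams predict_mask
#' @return `H x W` matrix of probabilities in (0, 1).
#' @export
predict_prob <- function(img, model) {
  m <- as_seg_model(model)
  if (dim(img)[1] != m$encoder_cfg$input_size) {
    img <- resize_image(img, m$encoder_cfg$input_size)
  }
  stages <- encode(img, m$encoder_cfg, m$params$encoder)
  decode(stages, m$params$decoder)
}

#' Write a color overlay of prediction errors
#'
#' True positives orange, false positives green, false negatives red, over
#' a dimmed copy of the input image.
#'
#' @param img Image array `H x W x 3`.
#' @param gt Binary ground-truth mask.
#' @param pred Binary predicted mask.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(img, gt, pred, path) {
  gt <- (gt > 0) * 1; pred <- (pred > 0) * 1
  out <- img * 0.5
  colors <- list(tp = c(1, 0.65, 0), fp = c(0, 0.8, 0), fn = c(1, 0, 0))
  sel <- list(tp = gt == 1 & pred == 1, fp = gt == 0 & pred == 1,
              fn = gt == 1 & pred == 0)
  for (nm in names(sel)) {
    for (c in 1:3) {
      plane <- out[, , c]
      plane[sel[[nm]]] <- colors[[nm]][c]
      out[, , c] <- plane
    }
  }
  png::writePNG(out, path)
  invisible(path)
}
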