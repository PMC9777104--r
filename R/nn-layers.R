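# Layer parameter containers, initializers, parameter tree utilities, and
# the two optimizers used by the training loops. Parameters live in nested
# named lists of double arrays; batch-norm running statistics live in
# environments so in-place updates survive the functional update cycle.

init_conv_w <- function(rng, k, cin, cout) {
  array(rng_rnorm(rng, k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

init_dw_w <- function(rng, k, c) {
  array(rng_rnorm(rng, k * k * c, sd = sqrt(2 / (k * k))), c(k, k, c))
}

init_convT_w <- function(rng, k, cout, cin) {
  array(rng_rnorm(rng, k * k * cout * cin, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cout, cin))
}

# (in x out) matrix applied as x %*% W.
init_linear_w <- function(rng, fin, fout) {
  matrix(rng_rnorm(rng, fin * fout, sd = sqrt(2 / fin)), fin, fout)
}

bn_new <- function(c) {
  st <- new.env(parent = emptyenv())
  st$mean <- rep(0, c)
  st$var <- rep(1, c)
  list(gamma = rep(1, c), beta = rep(0, c), rstate = st)
}

ln_new <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

# ---- parameter tree utilities ------------------------------------------

is_param_leaf <- function(x) is.double(x) && !is.list(x)

# Replace every double leaf by a registered autodiff leaf node (training) or
# a constant node (inference); environments and integer buffers pass through.
child_keys <- function(p) {
  nms <- names(p)
  if (is.null(nms)) as.character(seq_along(p)) else nms
}

join_prefix <- function(prefix, key) {
  if (nzchar(prefix)) paste0(prefix, "/", key) else key
}

wrap_params <- function(g, p, prefix = "", trainable = TRUE) {
  if (is_param_leaf(p)) {
    return(if (trainable) ad_leaf(g, p, prefix) else ad_const(g, p))
  }
  if (is.list(p)) {
    keys <- child_keys(p)
    out <- p
    for (i in seq_along(p)) {
      out[[i]] <- wrap_params(g, p[[i]], join_prefix(prefix, keys[i]), trainable)
    }
    return(out)
  }
  p
}

flatten_params <- function(p, prefix = "") {
  if (is_param_leaf(p)) {
    out <- list(p)
    names(out) <- prefix
    return(out)
  }
  if (is.list(p)) {
    keys <- child_keys(p)
    out <- list()
    for (i in seq_along(p)) {
      out <- c(out, flatten_params(p[[i]], join_prefix(prefix, keys[i])))
    }
    return(out)
  }
  list()
}

unflatten_params <- function(p, flat, prefix = "") {
  if (is_param_leaf(p)) {
    v <- flat[[prefix]]
    if (is.null(v)) return(p)
    dim(v) <- dim(p)
    return(v)
  }
  if (is.list(p)) {
    keys <- child_keys(p)
    for (i in seq_along(p)) {
      p[[i]] <- unflatten_params(p[[i]], flat, join_prefix(prefix, keys[i]))
    }
  }
  p
}

n_params <- function(p) {
  sum(vapply(flatten_params(p), length, numeric(1)))
}

# ---- optimizers ---------------------------------------------------------

opt_sgd <- function(lr = 0.001, momentum = 0.9) {
  o <- new.env(parent = emptyenv())
  o$lr <- lr; o$momentum <- momentum; o$vel <- list()
  class(o) <- c("opt_sgd", "optimizer")
  o
}

opt_adam <- function(lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  o <- new.env(parent = emptyenv())
  o$lr <- lr; o$beta1 <- beta1; o$beta2 <- beta2; o$eps <- eps
  o$m <- list(); o$v <- list(); o$t <- 0L
  class(o) <- c("opt_adam", "optimizer")
  o
}

opt_step <- function(opt, flat, grads) {
  if (inherits(opt, "opt_adam")) opt$t <- opt$t + 1L
  for (nm in names(flat)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    if (inherits(opt, "opt_sgd")) {
      v <- opt$vel[[nm]]
      if (is.null(v)) v <- 0
      v <- opt$momentum * v + gr
      opt$vel[[nm]] <- v
      flat[[nm]] <- flat[[nm]] - opt$lr * as.vector(v)
    } else {
      m <- opt$m[[nm]]; v <- opt$v[[nm]]
      if (is.null(m)) { m <- 0; v <- 0 }
      m <- opt$beta1 * m + (1 - opt$beta1) * gr
      v <- opt$beta2 * v + (1 - opt$beta2) * gr^2
      opt$m[[nm]] <- m; opt$v[[nm]] <- v
      mh <- m / (1 - opt$beta1^opt$t)
      vh <- v / (1 - opt$beta2^opt$t)
      flat[[nm]] <- flat[[nm]] - opt$lr * as.vector(mh / (sqrt(vh) + opt$eps))
    }
  }
  flat
}

# One optimization step over a nested parameter tree given leaf gradients
# keyed by flattened names.
apply_gradients <- function(params, grads, opt) {
  flat <- flatten_params(params)
  flat <- opt_step(opt, flat, grads)
  unflatten_params(params, flat)
}

# ---- composite layers ---------------------------------------------------

conv_bn_new <- function(rng, k, cin, cout) {
  list(w = init_conv_w(rng, k, cin, cout), bn = bn_new(cout))
}

# Forward helpers below expect a parameter tree already passed through
# wrap_params(), i.e. every double leaf is an ad node; integer metadata
# (strides, head counts, relative-position indices) passes through untouched.
nn_conv_bn_gelu <- function(g, x, p, stride = 1L, pad = 1L, dilation = 1L,
                            training = FALSE) {
  y <- ad_conv2d(g, x, p$w, stride = stride, pad = pad, dilation = dilation)
  y <- ad_batchnorm(g, y, p$bn$gamma, p$bn$beta, p$bn$rstate, training)
  ad_gelu(g, y)
}

# Squeeze-excitation on an H x W x C map; hidden width `ch`.
se_new <- function(rng, c, ch) {
  list(w1 = init_linear_w(rng, c, ch), b1 = rep(0, ch),
       w2 = init_linear_w(rng, ch, c), b2 = rep(0, c))
}

nn_se <- function(g, x, p) {
  s <- ad_gap(g, x)
  s <- ad_reshape(g, s, c(1L, length(s$value)))
  h <- ad_relu(g, ad_add_col_bias(g, ad_matmul(g, s, p$w1), p$b1))
  sc <- ad_sigmoid(g, ad_add_col_bias(g, ad_matmul(g, h, p$w2), p$b2))
  sc <- ad_reshape(g, sc, length(sc$value))
  ad_scale_channels(g, x, sc)
}

# Inverted-residual (MBConv) block: 1x1 expand -> 3x3 depthwise ->
# squeeze-excitation -> 1x1 project, residual when shapes match.
mbconv_new <- function(rng, cin, cout, stride, expand = 4L) {
  cexp <- cin * expand
  list(
    expand = conv_bn_new(rng, 1L, cin, cexp),
    dw_w = init_dw_w(rng, 3L, cexp),
    dw_bn = bn_new(cexp),
    se = se_new(rng, cexp, max(1L, cin %/% 4L)),
    proj = conv_bn_new(rng, 1L, cexp, cout),
    stride = as.integer(stride), cin = as.integer(cin), cout = as.integer(cout)
  )
}

nn_mbconv <- function(g, x, p, training = FALSE) {
  h <- nn_conv_bn_gelu(g, x, p$expand, stride = 1L, pad = 0L,
                       training = training)
  h <- ad_dwconv(g, h, p$dw_w, stride = p$stride, pad = 1L)
  h <- ad_batchnorm(g, h, p$dw_bn$gamma, p$dw_bn$beta, p$dw_bn$rstate, training)
  h <- ad_gelu(g, h)
  h <- nn_se(g, h, p$se)
  h <- ad_conv2d(g, h, p$proj$w, stride = 1L, pad = 0L)
  h <- ad_batchnorm(g, h, p$proj$bn$gamma, p$proj$bn$beta,
                    p$proj$bn$rstate, training)
  if (p$stride == 1L && p$cin == p$cout) h <- ad_add(g, h, x)
  h
}

# Relative-position index table for an H x W token grid: entry (q, k) holds
# the 1-based row of the (2H-1)(2W-1) bias table for offset (dq - dk).
rel_index <- function(H, W) {
  h <- rep(seq_len(H) - 1L, times = W)
  w <- rep(seq_len(W) - 1L, each = H)
  T <- H * W
  dh <- outer(h, h, "-") + H - 1L
  dw <- outer(w, w, "-") + W - 1L
  idx <- dh + (2L * H - 1L) * dw + 1L
  as.integer(idx)
}

transformer_block_new <- function(rng, c, nh, H, W, ffn_expansion = 4L) {
  list(
    ln1 = ln_new(c),
    wq = init_linear_w(rng, c, c), wk = init_linear_w(rng, c, c),
    wv = init_linear_w(rng, c, c), wo = init_linear_w(rng, c, c),
    bias_tab = matrix(rng_rnorm(rng, (2 * H - 1) * (2 * W - 1) * nh, sd = 0.02),
                      (2L * H - 1L) * (2L * W - 1L), nh),
    relidx = rel_index(H, W),
    ln2 = ln_new(c),
    ffn_w1 = init_linear_w(rng, c, c * ffn_expansion),
    ffn_b1 = rep(0, c * ffn_expansion),
    ffn_w2 = init_linear_w(rng, c * ffn_expansion, c),
    ffn_b2 = rep(0, c),
    nh = as.integer(nh), H = as.integer(H), W = as.integer(W)
  )
}

# Pre-norm transformer block over (T x C) tokens with multi-head
# self-attention carrying a learned 2D relative position bias.
nn_transformer_block <- function(g, x, p, return_attention = FALSE) {
  Tn <- nrow(x$value)
  C <- ncol(x$value)
  nh <- p$nh
  if (Tn != p$H * p$W) {
    stop("transformer block: sequence length ", Tn,
         " does not match the learned relative-bias table for ",
         p$H, "x", p$W, " tokens")
  }
  dh <- C %/% nh
  h <- ad_layernorm(g, x, p$ln1$gamma, p$ln1$beta)
  q <- ad_matmul(g, h, p$wq); k <- ad_matmul(g, h, p$wk); v <- ad_matmul(g, h, p$wv)
  bias_rows <- ad_gather_rows(g, p$bias_tab, p$relidx)
  heads <- vector("list", nh)
  attn_maps <- vector("list", nh)
  for (i in seq_len(nh)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    qi <- ad_cols(g, q, cols); ki <- ad_cols(g, k, cols); vi <- ad_cols(g, v, cols)
    a <- ad_matmul_bt(g, qi, ki)
    a <- ad_scale_const(g, a, 1 / sqrt(dh))
    b <- ad_reshape(g, ad_cols(g, bias_rows, i), c(Tn, Tn))
    a <- ad_add(g, a, b)
    a <- ad_softmax_rows(g, a)
    attn_maps[[i]] <- a
    heads[[i]] <- ad_matmul(g, a, vi)
  }
  att <- ad_matmul(g, ad_cbind(g, heads), p$wo)
  x <- ad_add(g, x, att)
  h2 <- ad_layernorm(g, x, p$ln2$gamma, p$ln2$beta)
  f <- ad_gelu(g, ad_add_col_bias(g, ad_matmul(g, h2, p$ffn_w1), p$ffn_b1))
  f <- ad_add_col_bias(g, ad_matmul(g, f, p$ffn_w2), p$ffn_b2)
  out <- ad_add(g, x, f)
  if (return_attention) list(out = out, attention = attn_maps) else out
}

ad_matmul_bt <- function(g, a, b) {
  ad_op(g, tcrossprod(a$value, b$value), list(a, b), function(gr) {
    ad_acc(a, gr %*% b$value)
    ad_acc(b, crossprod(gr, a$value))
  })
}

ad_scale_const <- function(g, a, k) {
  ad_op(g, a$value * k, list(a), function(gr) ad_acc(a, gr * k))
}
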