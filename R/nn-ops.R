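# Differentiable operations over the autodiff tape. Feature maps are numeric
# arrays dim c(H, W, C); token matrices are (H*W) x C with h varying fastest,
# so reshaping between the two is a zero-copy dim change.

# Length-1 operands act as bare scalars regardless of any dim attribute.
bc_val <- function(x) if (length(x) == 1L) as.vector(x) else x

ad_add <- function(g, a, b) {
  ad_op(g, bc_val(a$value) + bc_val(b$value), list(a, b), function(gr) {
    ad_acc(a, gr); ad_acc(b, gr)
  })
}

ad_sub <- function(g, a, b) {
  ad_op(g, bc_val(a$value) - bc_val(b$value), list(a, b), function(gr) {
    ad_acc(a, gr); ad_acc(b, -gr)
  })
}

ad_mul <- function(g, a, b) {
  av <- bc_val(a$value); bv <- bc_val(b$value)
  ad_op(g, av * bv, list(a, b), function(gr) {
    ad_acc(a, gr * bv); ad_acc(b, gr * av)
  })
}

ad_div <- function(g, a, b) {
  av <- bc_val(a$value); bv <- bc_val(b$value)
  ad_op(g, av / bv, list(a, b), function(gr) {
    ad_acc(a, gr / bv); ad_acc(b, -gr * av / (bv^2))
  })
}

ad_neg <- function(g, a) ad_op(g, -a$value, list(a), function(gr) ad_acc(a, -gr))

ad_log <- function(g, a) {
  ad_op(g, log(a$value), list(a), function(gr) ad_acc(a, gr / a$value))
}

ad_exp <- function(g, a) {
  v <- exp(a$value)
  ad_op(g, v, list(a), function(gr) ad_acc(a, gr * v))
}

ad_sqrt <- function(g, a) {
  v <- sqrt(a$value)
  ad_op(g, v, list(a), function(gr) ad_acc(a, gr * 0.5 / v))
}

ad_sum <- function(g, a) {
  d <- dim_or_len(a$value)
  ad_op(g, sum(a$value), list(a), function(gr) ad_acc(a, array(gr, dim = d)))
}

ad_mean <- function(g, a) {
  d <- dim_or_len(a$value)
  n <- length(a$value)
  ad_op(g, mean(a$value), list(a), function(gr) ad_acc(a, array(gr / n, dim = d)))
}

ad_clamp <- function(g, a, lo, hi) {
  keep <- a$value >= lo & a$value <= hi
  ad_op(g, pmin(pmax(a$value, lo), hi), list(a),
        function(gr) ad_acc(a, gr * keep))
}

ad_relu <- function(g, a) {
  keep <- a$value > 0
  ad_op(g, a$value * keep, list(a), function(gr) ad_acc(a, gr * keep))
}

ad_sigmoid <- function(g, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_op(g, s, list(a), function(gr) ad_acc(a, gr * s * (1 - s)))
}

# Exact GELU: x * Phi(x).
ad_gelu <- function(g, a) {
  x <- a$value
  ph <- stats::pnorm(x)
  ad_op(g, x * ph, list(a),
        function(gr) ad_acc(a, gr * (ph + x * stats::dnorm(x))))
}

ad_matmul <- function(g, a, b) {
  ad_op(g, a$value %*% b$value, list(a, b), function(gr) {
    ad_acc(a, gr %*% t(b$value))
    ad_acc(b, crossprod(a$value, gr))
  })
}

# Row-wise softmax of a matrix.
ad_softmax_rows <- function(g, a) {
  m <- a$value - apply(a$value, 1L, max)
  e <- exp(m)
  s <- e / rowSums(e)
  ad_op(g, s, list(a), function(gr) {
    ad_acc(a, s * (gr - rowSums(gr * s)))
  })
}

# Column subset of a matrix (contiguous or not); used for head splitting.
ad_cols <- function(g, a, idx) {
  nc <- ncol(a$value)
  ad_op(g, a$value[, idx, drop = FALSE], list(a), function(gr) {
    d <- matrix(0, nrow(gr), nc)
    d[, idx] <- gr
    ad_acc(a, d)
  })
}

ad_cbind <- function(g, nodes) {
  vals <- lapply(nodes, function(n) n$value)
  ncols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  ad_op(g, do.call(cbind, vals), nodes, function(gr) {
    for (i in seq_along(nodes)) {
      ad_acc(nodes[[i]], gr[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

# Row gather with scatter-add backward; used for relative position bias.
ad_gather_rows <- function(g, tab, idx) {
  nr <- nrow(tab$value)
  ad_op(g, tab$value[idx, , drop = FALSE], list(tab), function(gr) {
    agg <- rowsum(gr, group = idx)
    d <- matrix(0, nr, ncol(gr))
    d[as.integer(rownames(agg)), ] <- agg
    ad_acc(tab, d)
  })
}

# Channel concatenation of H x W x C_i maps.
ad_concat_c <- function(g, nodes) {
  dims <- lapply(nodes, function(n) dim(n$value))
  H <- dims[[1]][1]; W <- dims[[1]][2]
  cs <- vapply(dims, function(d) d[3], numeric(1))
  ends <- cumsum(cs); starts <- ends - cs + 1
  out <- array(0, c(H, W, sum(cs)))
  for (i in seq_along(nodes)) out[, , starts[i]:ends[i]] <- nodes[[i]]$value
  ad_op(g, out, nodes, function(gr) {
    for (i in seq_along(nodes)) {
      ad_acc(nodes[[i]], gr[, , starts[i]:ends[i], drop = FALSE])
    }
  })
}

# Global average pool: H x W x C -> length-C vector.
ad_gap <- function(g, a) {
  d <- dim(a$value)
  n <- d[1] * d[2]
  v <- colMeans(matrix(a$value, n, d[3]))
  ad_op(g, v, list(a), function(gr) {
    ad_acc(a, array(rep(gr / n, each = n), dim = d))
  })
}

# Multiply each channel of x (H x W x C) by a scalar from vector s (length C).
ad_scale_channels <- function(g, x, s) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  sv <- rep(s$value, each = n)
  ad_op(g, x$value * array(sv, d), list(x, s), function(gr) {
    ad_acc(x, gr * array(sv, d))
    ad_acc(s, colSums(matrix(gr * x$value, n, d[3])))
  })
}

# Add a per-channel bias to x (H x W x C).
ad_add_channel_bias <- function(g, x, b) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  ad_op(g, x$value + array(rep(b$value, each = n), d), list(x, b), function(gr) {
    ad_acc(x, gr)
    ad_acc(b, colSums(matrix(gr, n, d[3])))
  })
}

# Add a per-column bias to a (T x C) matrix.
ad_add_col_bias <- function(g, x, b) {
  ad_op(g, sweep(x$value, 2L, b$value, "+"), list(x, b), function(gr) {
    ad_acc(x, gr)
    ad_acc(b, colSums(gr))
  })
}

# Multiply every column of x (T x C) by coefficient vector v (length T).
ad_scale_rows <- function(g, x, v) {
  vv <- as.vector(v$value)
  ad_op(g, x$value * vv, list(x, v), function(gr) {
    ad_acc(x, gr * vv)
    ad_acc(v, rowSums(gr * x$value))
  })
}

ad_reshape <- function(g, a, newdim) {
  olddim <- dim_or_len(a$value)
  v <- a$value
  dim(v) <- newdim
  ad_op(g, v, list(a), function(gr) {
    dim(gr) <- olddim
    ad_acc(a, gr)
  })
}

# 2D convolution via im2col + BLAS. x: H x W x Cin, w: k x k x Cin x Cout.
ad_conv2d <- function(g, x, w, b = NULL, stride = 1L, pad = 0L, dilation = 1L) {
  d <- dim(x$value)
  wd <- dim(w$value)
  k <- wd[1]
  if (wd[3] != d[3]) {
    stop("conv2d: input has ", d[3], " channels but weight expects ", wd[3])
  }
  cols <- im2col_cpp(x$value, d[1], d[2], d[3], k, stride, pad, dilation)
  Wm <- matrix(w$value, k * k * wd[3], wd[4])
  y <- crossprod(cols, Wm)
  ho <- (d[1] + 2 * pad - dilation * (k - 1) - 1) %/% stride + 1
  wo <- (d[2] + 2 * pad - dilation * (k - 1) - 1) %/% stride + 1
  if (!is.null(b)) y <- sweep(y, 2L, b$value, "+")
  dim(y) <- c(ho, wo, wd[4])
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ad_op(g, y, parents, function(gr) {
    grm <- matrix(gr, ho * wo, wd[4])
    if (!is.null(b)) ad_acc(b, colSums(grm))
    dW <- cols %*% grm
    dim(dW) <- wd
    ad_acc(w, dW)
    if (x$requires) {
      dcols <- Wm %*% t(grm)
      ad_acc(x, col2im_cpp(dcols, d[1], d[2], d[3], k, stride, pad, dilation))
    }
  })
}

# Depthwise 2D convolution. w: k x k x C.
ad_dwconv <- function(g, x, w, stride = 1L, pad = 0L, dilation = 1L) {
  d <- dim(x$value)
  k <- dim(w$value)[1]
  y <- dwconv_fwd_cpp(x$value, d[1], d[2], d[3], w$value, k, stride, pad, dilation)
  ad_op(g, y, list(x, w), function(gr) {
    ad_acc(w, dwconv_bwd_weight_cpp(gr, x$value, d[1], d[2], d[3],
                                    k, stride, pad, dilation))
    if (x$requires) {
      ad_acc(x, dwconv_bwd_input_cpp(gr, d[1], d[2], d[3], w$value,
                                     k, stride, pad, dilation))
    }
  })
}

# Transposed convolution (kernel k, stride s, padding p), the adjoint map of
# the corresponding forward convolution. w: k x k x Cout x Cin.
ad_conv2d_transpose <- function(g, x, w, b = NULL, stride = 2L, pad = 1L) {
  d <- dim(x$value)
  wd <- dim(w$value)
  k <- wd[1]
  if (wd[4] != d[3]) {
    stop("conv2d_transpose: input has ", d[3], " channels but weight expects ", wd[4])
  }
  ho <- (d[1] - 1) * stride - 2 * pad + k
  wo <- (d[2] - 1) * stride - 2 * pad + k
  Wm <- matrix(w$value, k * k * wd[3], wd[4])
  Xmat <- matrix(x$value, d[1] * d[2], d[3])
  colsmat <- Wm %*% t(Xmat)
  y <- col2im_cpp(colsmat, ho, wo, wd[3], k, stride, pad, 1L)
  if (!is.null(b)) {
    y <- y + array(rep(b$value, each = ho * wo), c(ho, wo, wd[3]))
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ad_op(g, y, parents, function(gr) {
    colsg <- im2col_cpp(gr, ho, wo, wd[3], k, stride, pad, 1L)
    if (!is.null(b)) ad_acc(b, colSums(matrix(gr, ho * wo, wd[3])))
    dW <- colsg %*% Xmat
    dim(dW) <- wd
    ad_acc(w, dW)
    if (x$requires) {
      dX <- crossprod(colsg, Wm)
      dim(dX) <- d
      ad_acc(x, dX)
    }
  })
}

ad_maxpool <- function(g, x, k = 2L, stride = 2L) {
  d <- dim(x$value)
  r <- maxpool_fwd_cpp(x$value, d[1], d[2], d[3], k, stride)
  ad_op(g, r$y, list(x), function(gr) {
    ad_acc(x, maxpool_bwd_cpp(gr, r$idx, d[1], d[2], d[3]))
  })
}

# Nearest-neighbour x2 upsampling of an H x W x C map.
ad_upsample2 <- function(g, x) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  ad_op(g, x$value[ri, ci, , drop = FALSE], list(x), function(gr) {
    o <- seq(1L, 2L * d[1], by = 2L)
    e <- seq(1L, 2L * d[2], by = 2L)
    dx <- gr[o, e, , drop = FALSE] + gr[o + 1L, e, , drop = FALSE] +
      gr[o, e + 1L, , drop = FALSE] + gr[o + 1L, e + 1L, , drop = FALSE]
    ad_acc(x, dx)
  })
}

# Batch normalization over the spatial extent of one H x W x C map, with
# running statistics (momentum 0.1) used at inference. `rstate` is an
# environment with fields mean and var, updated in place during training.
ad_batchnorm <- function(g, x, gamma, beta, rstate, training,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  X <- matrix(x$value, n, d[3])
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu, "-")
    v <- colMeans(xc^2)
    rstate$mean <- (1 - momentum) * rstate$mean + momentum * mu
    unb <- if (n > 1) n / (n - 1) else 1
    rstate$var <- (1 - momentum) * rstate$var + momentum * v * unb
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2L, inv, "*")
    y <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
    dim(y) <- d
    ad_op(g, y, list(x, gamma, beta), function(gr) {
      G <- matrix(gr, n, d[3])
      ad_acc(gamma, colSums(G * xhat))
      ad_acc(beta, colSums(G))
      if (x$requires) {
        dxh <- sweep(G, 2L, gamma$value, "*")
        t1 <- sweep(dxh, 2L, colMeans(dxh), "-")
        t2 <- sweep(xhat, 2L, colMeans(dxh * xhat), "*")
        dX <- sweep(t1 - t2, 2L, inv, "*")
        dim(dX) <- d
        ad_acc(x, dX)
      }
    })
  } else {
    inv <- 1 / sqrt(rstate$var + eps)
    xhat <- sweep(sweep(X, 2L, rstate$mean, "-"), 2L, inv, "*")
    y <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
    dim(y) <- d
    ad_op(g, y, list(x, gamma, beta), function(gr) {
      G <- matrix(gr, n, d[3])
      ad_acc(gamma, colSums(G * xhat))
      ad_acc(beta, colSums(G))
      if (x$requires) {
        dX <- sweep(sweep(G, 2L, gamma$value, "*"), 2L, inv, "*")
        dim(dX) <- d
        ad_acc(x, dX)
      }
    })
  }
}

# Layer normalization over the channel dimension of a (T x C) token matrix.
ad_layernorm <- function(g, x, gamma, beta, eps = 1e-5) {
  X <- x$value
  C <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  ad_op(g, y, list(x, gamma, beta), function(gr) {
    ad_acc(gamma, colSums(gr * xhat))
    ad_acc(beta, colSums(gr))
    if (x$requires) {
      dxh <- sweep(gr, 2L, gamma$value, "*")
      dX <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * inv
      ad_acc(x, dX)
    }
  })
}
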