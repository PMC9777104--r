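make_whdc <- function(channels = 8L, rates = c(3L, 6L, 9L, 18L), ratio = 8L,
                      seed = 1) {
  cfg <- whdc_config(channels, dilation_rates = rates, reduction_ratio = ratio)
  list(cfg = cfg, params = whdc_init(cfg, seed))
}

test_that("whdc config validation", {
  expect_error(whdc_config(8L, dilation_rates = c(3, 3, 9, 18)), "increasing")
  expect_error(whdc_config(8L, dilation_rates = c(-1, 3, 9, 18)), "increasing|positive")
  expect_error(whdc_config(0L), "channels")
})

test_that("dilated branches preserve shape for every rate, including rates beyond the map", {
  w <- make_whdc()
  for (i in seq_along(w$cfg$dilation_rates)) {
    rate <- w$cfg$dilation_rates[i]
    for (hw in list(c(32L, 32L), c(12L, 20L))) {
      x <- array(rnorm(hw[1] * hw[2] * 8), c(hw[1], hw[2], 8))
      y <- dilated_branch(x, rate, w$params$branches[[i]], training = TRUE)
      expect_equal(dim(y), dim(x))
    }
  }
  # effective kernel span at rate 18 is 3 + 2*17 = 37 > 32: zero padding covers it
  expect_equal(3 + (3 - 1) * (18 - 1), 37)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_error(dilated_branch(x, 3, w$params$branches[[1]]), "channel mismatch")
})

test_that("all-zero input propagates to a constant map through conv/BN/GELU", {
  w <- make_whdc(channels = 4L)
  x <- array(0, c(8, 8, 4))
  y <- dilated_branch(x, 3, w$params$branches[[1]], training = FALSE)
  expect_equal(length(unique(round(as.vector(y), 12))), 1L)
})

test_that("branch gates are sigmoid read-outs of pooled branch features", {
  w <- make_whdc()
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  gate <- branch_gate(x, w$params$gates[[1]])
  expect_true(gate > 0 && gate < 1)
  # zero weights and bias give exactly sigmoid(0) = 0.5
  g0 <- branch_gate(x, list(a = matrix(0, 8, 1), b = 0))
  expect_equal(as.vector(g0), 0.5)
  # closed form on a 1x1x1 map: sigmoid(a v + b)
  v <- 0.7; a <- 1.3; b <- -0.4
  g1 <- branch_gate(array(v, c(1, 1, 1)), list(a = matrix(a, 1, 1), b = b))
  expect_equal(as.vector(g1), 1 / (1 + exp(-(a * v + b))), tolerance = 1e-12)
  # saturation toward 1 with a large bias
  gbig <- branch_gate(x, list(a = matrix(0, 8, 1), b = 50))
  expect_gt(as.vector(gbig), 1 - 1e-12)
})

test_that("channel attention matches a by-hand two-channel evaluation", {
  x <- array(c(rep(1, 4), rep(3, 4)), c(2, 2, 2))
  # squeeze = (1, 3); w1: 2 -> 1, w2: 1 -> 2
  params <- list(w1 = matrix(c(0.5, -0.25), 2, 1), b1 = 0.1,
                 w2 = matrix(c(2, -1), 1, 2), b2 = c(0, 0.2))
  h <- max(0, 1 * 0.5 + 3 * (-0.25) + 0.1)
  scales <- 1 / (1 + exp(-(c(2, -1) * h + c(0, 0.2))))
  got <- channel_attention(x, params, reduction_ratio = 2L)
  expect_equal(got[, , 1], matrix(1 * scales[1], 2, 2), tolerance = 1e-12)
  expect_equal(got[, , 2], matrix(3 * scales[2], 2, 2), tolerance = 1e-12)
  # zero-weight attention halves every channel, and scales never exceed 1
  p0 <- list(w1 = matrix(0, 2, 1), b1 = 0, w2 = matrix(0, 1, 2), b2 = c(0, 0))
  expect_equal(channel_attention(x, p0, 2L), x * 0.5, tolerance = 1e-12)
  p <- cam_init(8L, 4L, rng = 3)
  xr <- array(abs(rnorm(4 * 4 * 8)), c(4, 4, 8))
  y <- channel_attention(xr, p, 4L)
  expect_true(all(abs(y) <= abs(xr)))
  expect_error(channel_attention(array(1, c(2, 2, 2)), p, 16L), "reduction_ratio")
})

test_that("whdc_forward preserves shape and responds to every branch", {
  w <- make_whdc()
  for (hw in list(c(16L, 16L), c(24L, 8L))) {
    x <- array(rnorm(hw[1] * hw[2] * 8) * 0.5, c(hw[1], hw[2], 8))
    y <- whdc_forward(x, w$cfg, w$params, training = TRUE)
    expect_equal(dim(y), dim(x))
  }
  x <- array(rnorm(12 * 12 * 8) * 0.5, c(12, 12, 8))
  base <- whdc_forward(x, w$cfg, w$params, training = TRUE)
  # finite-difference probe: output is sensitive to each branch's conv weights
  # (perturb the central tap: at rate 18 on a small map the outer taps only
  # ever see zero padding)
  for (i in 1:4) {
    p2 <- w$params
    p2$branches[[i]]$w[2, 2, 1, 1] <- p2$branches[[i]]$w[2, 2, 1, 1] + 1e-3
    y2 <- whdc_forward(x, w$cfg, p2, training = TRUE)
    expect_gt(max(abs(y2 - base)), 0)
  }
})

test_that("gates forced shut reduce whdc to channel attention on the pass-through slice", {
  w <- make_whdc(channels = 4L, rates = c(1L, 2L, 3L, 4L), ratio = 4L)
  p <- w$params
  for (i in 1:4) p$gates[[i]]$b <- -1e4   # sigmoid -> 0: branches contribute nothing
  # 1x1 projection selecting concat channels 17..20 (the input slice)
  proj_w <- array(0, c(1, 1, 20, 4))
  for (c in 1:4) proj_w[1, 1, 16 + c, c] <- 1
  p$proj$w <- proj_w
  p$proj$b <- rep(0, 4)
  x <- array(abs(rnorm(8 * 8 * 4)), c(8, 8, 4))
  got <- whdc_forward(x, w$cfg, p, training = TRUE)
  # reference: channel attention over the same concatenation, input slice
  branches <- list()
  prev <- x
  for (i in 1:4) {
    prev <- dilated_branch(prev, w$cfg$dilation_rates[i], p$branches[[i]],
                           training = TRUE)
    branches[[i]] <- prev * 0   # gated to zero
  }
  cat5 <- array(0, c(8, 8, 20))
  cat5[, , 17:20] <- x
  ref <- channel_attention(cat5, p$cam, w$cfg$reduction_ratio)[, , 17:20]
  expect_equal(got, ref, tolerance = 1e-8)
})

test_that("permuting the dilation-rate cascade changes the output", {
  cfg1 <- whdc_config(6L, dilation_rates = c(3L, 6L, 9L, 18L), reduction_ratio = 6L)
  p <- whdc_init(cfg1, 2)
  cfg2 <- cfg1
  cfg2$dilation_rates <- c(18L, 9L, 6L, 3L)
  x <- array(rnorm(16 * 16 * 6), c(16, 16, 6))
  y1 <- whdc_forward(x, cfg1, p, training = TRUE)
  y2 <- whdc_forward(x, cfg2, p, training = TRUE)
  expect_gt(max(abs(y1 - y2)), 1e-6)
})
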