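test_that("encoder config validation", {
  expect_error(encoder_config("tiny", input_size = 100L), "divisible by 32")
  expect_error(encoder_config("tiny", stage_channels = c(32L, 16L, 8L, 4L, 2L)),
               "nondecreasing")
  expect_error(encoder_config("tiny", stage_channels = c(16L, 24L, 32L)),
               "length 5")
})

test_that("stage sides halve at every stage (downsampling law)", {
  cfg <- encoder_config("tiny", input_size = 64L)
  params <- encoder_init(cfg, 1)
  img <- random_image(64)
  st <- encode(img, cfg, params)
  expect_equal(sapply(st[c("s0", "s1", "s2", "s3", "s4")], function(s) dim(s)[1]),
               c(s0 = 32, s1 = 16, s2 = 8, s3 = 4, s4 = 2))
  expect_equal(sapply(st[c("s0", "s1", "s2", "s3", "s4")], function(s) dim(s)[3]),
               c(s0 = 16, s1 = 24, s2 = 32, s3 = 64, s4 = 128))
  expect_length(st$bottleneck, 128L)
  expect_error(encode(random_image(32), cfg, params), "expects 64x64")
})

test_that("per-stage surfaces agree with the chained encoder", {
  cfg <- encoder_config("tiny", input_size = 64L)
  params <- encoder_init(cfg, 2)
  img <- random_image(64, seed = 5)
  st <- encode(img, cfg, params)
  s0 <- conv_stem(img, cfg, params)
  expect_equal(s0, st$s0, tolerance = 1e-12)
  s1 <- mbconv_stage(s0, 1L, cfg, params)
  expect_equal(s1, st$s1, tolerance = 1e-12)
  s2 <- mbconv_stage(s1, 2L, cfg, params)
  expect_equal(s2, st$s2, tolerance = 1e-12)
  s3 <- transformer_stage(s2, 3L, cfg, params)
  expect_equal(s3, st$s3, tolerance = 1e-12)
  s4 <- transformer_stage(s3, 4L, cfg, params)
  expect_equal(s4, st$s4, tolerance = 1e-12)
  expect_equal(st$bottleneck, colMeans(matrix(s4, 4, 128)), tolerance = 1e-12)
})

test_that("inference is deterministic", {
  cfg <- encoder_config("tiny", input_size = 64L)
  params <- encoder_init(cfg, 3)
  img <- random_image(64, seed = 9)
  expect_identical(encode(img, cfg, params), encode(img, cfg, params))
})

test_that("the full preset has more parameters than the tiny preset", {
  n_tiny <- stainseg:::n_params(encoder_init(encoder_config("tiny", 64L), 1))
  n_full <- stainseg:::n_params(encoder_init(encoder_config("full", 64L), 1))
  expect_gt(n_full, n_tiny)
})

test_that("the WHDC block in S1 is active (ablation changes the output)", {
  cfg <- encoder_config("tiny", input_size = 64L)
  params <- encoder_init(cfg, 4)
  img <- random_image(64, seed = 2)
  s0 <- conv_stem(img, cfg, params)
  g <- stainseg:::ad_graph()
  pn <- stainseg:::wrap_params(g, params$s1, trainable = FALSE)
  with_whdc <- stainseg:::nn_mbconv_stage(g, stainseg:::ad_const(g, s0), cfg, pn,
                                          1L, use_whdc = TRUE)$value
  without <- stainseg:::nn_mbconv_stage(g, stainseg:::ad_const(g, s0), cfg, pn,
                                        1L, use_whdc = FALSE)$value
  expect_gt(max(abs(with_whdc - without)), 1e-6)
})

test_that("attention weights are row-normalized and a zeroed FFN/projection leaves tokens unchanged", {
  rng <- rng_stream(8)
  p <- stainseg:::transformer_block_new(rng, 8L, 2L, 4L, 4L)
  x <- matrix(rnorm(16 * 8), 16, 8)
  g <- stainseg:::ad_graph()
  pn <- stainseg:::wrap_params(g, p, trainable = FALSE)
  out <- stainseg:::nn_transformer_block(g, stainseg:::ad_const(g, x), pn,
                                         return_attention = TRUE)
  for (a in out$attention) {
    expect_equal(rowSums(a$value), rep(1, 16), tolerance = 1e-12)
  }
  p0 <- p
  p0$wo <- p$wo * 0
  p0$ffn_w2 <- p$ffn_w2 * 0
  p0$ffn_b2 <- p$ffn_b2 * 0
  g2 <- stainseg:::ad_graph()
  pn0 <- stainseg:::wrap_params(g2, p0, trainable = FALSE)
  out0 <- stainseg:::nn_transformer_block(g2, stainseg:::ad_const(g2, x), pn0)
  expect_equal(out0$value, x, tolerance = 1e-12)
})

test_that("transformer stages reject a mismatched sequence length", {
  cfg <- encoder_config("tiny", input_size = 64L)
  params <- encoder_init(cfg, 5)
  bad <- array(rnorm(16 * 16 * 32), c(16, 16, 32))  # pools to 8x8, table is 4x4
  expect_error(transformer_stage(bad, 3L, cfg, params), "relative-bias")
})

test_that("checkpoints round-trip parameters, config and running stats", {
  cfg <- encoder_config("tiny", input_size = 64L)
  params <- encoder_init(cfg, 6)
  img <- random_image(64, seed = 3)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(f, "encoder", cfg, params)
  ck <- load_checkpoint(f)
  expect_identical(ck$kind, "encoder")
  expect_identical(unclass(ck$config), unclass(cfg))
  expect_identical(stainseg:::flatten_params(ck$params),
                   stainseg:::flatten_params(params))
  expect_identical(encode(img, cfg, ck$params), encode(img, cfg, params))
  expect_identical(ck$params$s0$conv1$bn$rstate$mean,
                   params$s0$conv1$bn$rstate$mean)
  expect_error(load_checkpoint(withr::local_tempfile(fileext = ".rds",
                                                     lines = "x")))
  plain <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), plain)
  expect_error(load_checkpoint(plain), "not a stainseg checkpoint")
})

test_that("stage heatmap dumps write one PNG per stage", {
  cfg <- encoder_config("tiny", input_size = 64L)
  params <- encoder_init(cfg, 7)
  st <- encode(random_image(64, seed = 4), cfg, params)
  d <- withr::local_tempdir()
  paths <- dump_stage_heatmaps(st, d)
  expect_length(paths, 5L)
  expect_true(all(file.exists(paths)))
  hm <- png::readPNG(paths[1])
  expect_equal(dim(hm), c(32, 32))
})
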