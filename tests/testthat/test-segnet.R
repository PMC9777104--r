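test_that("attention gate coefficients are sigmoid-bounded and zero params halve the skip", {
  rng <- rng_stream(4)
  p <- attention_gate_init(3L, 5L, rng)
  skip <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  gating <- array(rnorm(4 * 4 * 5), c(4, 4, 5))
  out <- attention_gate(skip, gating, p)
  expect_equal(dim(out), dim(skip))
  ratio <- out / skip
  expect_true(all(ratio > 0 & ratio < 1))
  p0 <- list(wx = matrix(0, 3, 1), wg = matrix(0, 5, 1), b = 0,
             psi = matrix(0, 1, 1), bpsi = 0)
  expect_equal(attention_gate(skip, gating, p0), skip / 2, tolerance = 1e-12)
  expect_error(attention_gate(skip, array(rnorm(12), c(2, 2, 3)), p0),
               "match the skip size")
})

test_that("attention gate matches by-hand arithmetic on a 1-channel 2x2 toy", {
  skip <- array(c(1, 2, 3, 4), c(2, 2, 1))
  gating <- array(0.5, c(1, 1, 1))
  p <- list(wx = matrix(0.2, 1, 1), wg = matrix(-0.3, 1, 1), b = 0.1,
            psi = matrix(1.5, 1, 1), bpsi = -0.2)
  # gating upsamples to 2x2 of 0.5; per pixel q = relu(0.2 s - 0.15 + 0.1)
  q <- pmax(0.2 * c(1, 2, 3, 4) - 0.3 * 0.5 + 0.1, 0)
  coeff <- 1 / (1 + exp(-(1.5 * q - 0.2)))
  expect_equal(as.vector(attention_gate(skip, gating, p)),
               c(1, 2, 3, 4) * coeff, tolerance = 1e-12)
})

test_that("decode emits a full-resolution probability map", {
  cfg <- encoder_config("tiny", input_size = 64L)
  enc <- encoder_init(cfg, 1)
  dec <- stainseg:::decoder_init(cfg, seg_config(), rng_stream(2))
  st <- encode(random_image(64), cfg, enc)
  prob <- decode(st, dec)
  expect_equal(dim(prob), c(64L, 64L))
  expect_true(all(prob > 0 & prob < 1))
  expect_identical(decode(st, dec), prob)
})

test_that("loss closed forms", {
  expect_equal(bce_loss(matrix(1), matrix(0.5)), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(matrix(1), matrix(1e-7)), -log(1e-7), tolerance = 1e-6)
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(bce_loss(y, y), 1e-6)
  expect_lt(dice_loss(y, y), 1e-6)
  expect_gt(dice_loss(y, 1 - y), 1 - 1e-5)
  # two positive pixels, prediction hits exactly one: 1 - 2/3
  y2 <- matrix(0, 2, 2); y2[1, 1] <- 1; y2[2, 2] <- 1
  t2 <- matrix(0, 2, 2); t2[1, 1] <- 1
  expect_equal(dice_loss(y2, t2), 1 / 3, tolerance = 1e-5)
  # both-empty masks are a perfect prediction
  expect_lt(dice_loss(matrix(0, 2, 2), matrix(0, 2, 2)), 1e-6)
  expect_equal(combined_loss(y, y * 0.5, gamma = 1), bce_loss(y, y * 0.5))
  expect_equal(combined_loss(y, y * 0.5, gamma = 0), dice_loss(y, y * 0.5))
  expect_equal(0.4 * 1.0 + 0.6 * 0.5, 0.7)
  expect_error(bce_loss(matrix(1), matrix(0.5, 2, 2)), "differ")
})

test_that("losses match scalar-loop oracles on random inputs", {
  rng <- rng_stream(31)
  for (rep in 1:50) {
    y <- matrix(stainseg:::rng_int(rng, 64, 0, 1), 8, 8)
    t <- matrix(stainseg:::rng_runif(rng, 64, 1e-4, 1 - 1e-4), 8, 8)
    gamma <- stainseg:::rng_runif(rng, 1)
    expect_equal(bce_loss(y, t), oracle_bce(y, t), tolerance = 1e-9)
    expect_equal(dice_loss(y, t), oracle_dice_loss(y, t), tolerance = 1e-9)
    expect_equal(combined_loss(y, t, gamma),
                 gamma * oracle_bce(y, t) + (1 - gamma) * oracle_dice_loss(y, t),
                 tolerance = 1e-9)
  }
})

test_that("the tape-level losses equal the reference implementations", {
  rng <- rng_stream(32)
  for (rep in 1:5) {
    y <- matrix(stainseg:::rng_int(rng, 64, 0, 1), 8, 8)
    t <- matrix(stainseg:::rng_runif(rng, 64, 1e-4, 1 - 1e-4), 8, 8)
    g <- stainseg:::ad_graph()
    tn <- stainseg:::ad_const(g, t)
    yn <- stainseg:::ad_const(g, y)
    expect_equal(stainseg:::nn_bce(g, yn, tn)$value, bce_loss(y, t), tolerance = 1e-12)
    expect_equal(stainseg:::nn_dice(g, yn, tn)$value, dice_loss(y, t), tolerance = 1e-12)
    expect_equal(stainseg:::nn_combined(g, yn, tn, 0.4)$value,
                 combined_loss(y, t, 0.4), tolerance = 1e-12)
  }
})

test_that("combined loss is monotone in gamma according to the BCE/Dice ordering", {
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  t_conf <- matrix(c(0.6, 0.4, 0.6, 0.4), 2, 2)
  gammas <- seq(0, 1, by = 0.25)
  vals <- sapply(gammas, function(g) combined_loss(y, t_conf, g))
  if (bce_loss(y, t_conf) > dice_loss(y, t_conf)) {
    expect_true(all(diff(vals) > 0))
  } else {
    expect_true(all(diff(vals) < 0))
  }
  # and a case with Dice > BCE flips the direction
  y1 <- matrix(c(1, 0, 0, 0), 2, 2)
  t_low <- matrix(c(0.3, 0.001, 0.001, 0.001), 2, 2)
  expect_gt(dice_loss(y1, t_low), bce_loss(y1, t_low))
  vals2 <- sapply(gammas, function(g) combined_loss(y1, t_low, g))
  expect_true(all(diff(vals2) < 0))
})

test_that("segmentation training runs, logs losses, and distinguishes init arms", {
  d <- withr::local_tempdir()
  man <- generate_corpus(6, tiny_spec(), list(stain_domain()), d, seed = 41)
  mdf <- utils::read.csv(man)
  ecfg <- encoder_config("tiny", input_size = 64L)
  pre <- suppressMessages(
    pretrain(mdf[5:6, , drop = FALSE], ecfg,
             contrastive_config(epochs = 1L, seed = 6),
             out_dir = withr::local_tempdir()))
  out <- withr::local_tempdir()
  cfg3 <- seg_config(epochs = 3L, batch_size = 2L, seed = 7)
  res_pre <- train_segmentation(mdf[1:4, ], checkpoint = pre$checkpoint,
                                cfg = cfg3, out_dir = out)
  expect_equal(nrow(res_pre$loss_log), 3L)
  expect_true(file.exists(file.path(out, "train_loss.csv")))
  expect_true(file.exists(res_pre$checkpoint))
  res_rnd <- train_segmentation(mdf[1:4, ], encoder_cfg = ecfg,
                                cfg = seg_config(epochs = 1L, batch_size = 2L, seed = 7),
                                out_dir = withr::local_tempdir())
  # pretrained vs random initialization are different parameter sets
  f_pre <- stainseg:::flatten_params(load_checkpoint(pre$checkpoint)$params)
  f_rnd <- stainseg:::flatten_params(
    encoder_init(ecfg, rng_stream(derive_seed(7L, "seg-init"))))
  expect_false(identical(f_pre, f_rnd))
  # config mismatch between checkpoint and requested encoder is refused
  bad_cfg <- encoder_config("tiny", input_size = 96L)
  expect_error(train_segmentation(mdf[1:4, ], checkpoint = pre$checkpoint,
                                  encoder_cfg = bad_cfg, cfg = cfg3),
               "input_size")
  expect_error(train_segmentation(list(), encoder_cfg = ecfg, cfg = cfg3),
               "empty")
})

test_that("predict_mask applies the >= threshold convention", {
  d <- withr::local_tempdir()
  man <- generate_corpus(2, tiny_spec(), list(stain_domain()), d, seed = 43)
  mdf <- utils::read.csv(man)
  ecfg <- encoder_config("tiny", input_size = 64L)
  res <- train_segmentation(mdf, encoder_cfg = ecfg,
                            cfg = seg_config(epochs = 1L, batch_size = 2L, seed = 9),
                            out_dir = withr::local_tempdir())
  img <- load_image(mdf$image[1])
  prob <- predict_prob(img, res)
  m_def <- predict_mask(img, res)
  expect_identical(m_def, (prob >= 0.5) * 1L)
  expect_true(all(predict_mask(img, res, threshold = 1e-12) == 1L))
  # exact-boundary rule: a threshold equal to an attained probability keeps it
  thr <- prob[17, 23]
  m_thr <- predict_mask(img, res, threshold = thr)
  expect_identical(m_thr[17, 23], 1L)
  # model also loads from its checkpoint path
  m_ck <- predict_mask(img, res$checkpoint)
  expect_identical(m_ck, m_def)
})

test_that("overlay writer colors TP orange, FP green, FN red", {
  img <- array(0, c(4, 4, 3))
  gt <- matrix(c(1, 1, 0, 0), 4, 4)
  pred <- matrix(c(1, 0, 1, 0), 4, 4)
  f <- withr::local_tempfile(fileext = ".png")
  write_overlay(img, gt, pred, f)
  out <- png::readPNG(f)
  expect_equal(out[1, 1, ], c(1, 0.65, 0), tolerance = 0.01)  # TP
  expect_equal(out[3, 1, ], c(0, 0.8, 0), tolerance = 0.01)   # FP
  expect_equal(out[2, 1, ], c(1, 0, 0), tolerance = 0.01)     # FN
})
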