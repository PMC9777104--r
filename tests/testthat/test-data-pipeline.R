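test_that("image and mask I/O round-trip exactly", {
  p <- generate_patch(tiny_spec(), 1)
  f <- withr::local_tempfile(fileext = ".png")
  save_image(p$image, f)
  expect_identical(load_image(f), p$image)
  # 16-bit masks preserve large labels exactly
  m <- matrix(0L, 16, 16)
  m[2:5, 2:5] <- 300L
  m[10:12, 10:12] <- 65535L
  fm <- withr::local_tempfile(fileext = ".tif")
  save_mask(m, fm)
  expect_identical(load_mask(fm), m)
})

test_that("unreadable rasters raise I/O errors", {
  f <- withr::local_tempfile(fileext = ".png")
  writeLines("this is not a png", f)
  expect_error(load_image(f), "failed to read")
  expect_error(load_image("no/such/file.png"), "does not exist")
  expect_error(load_mask("no/such/file.tif"), "does not exist")
})

test_that("resizing contracts hold", {
  p <- generate_patch(tiny_spec(), 1)
  expect_identical(resize_image(p$image, 64), p$image)
  const <- array(0.25, c(32, 32, 3))
  up <- resize_image(const, 64)
  expect_true(all(abs(up - 0.25) < 1e-12))
  r <- resize_image(p$image, 128)
  expect_equal(dim(r), c(128L, 128L, 3L))
  # nearest-neighbor mask resize never invents labels
  m <- p$mask
  for (target in c(32L, 96L, 128L)) {
    rm <- resize_mask(m, target)
    expect_equal(dim(rm), c(target, target))
    expect_true(all(unique(as.vector(rm)) %in% unique(as.vector(m))))
  }
})

test_that("grid_patches tiles exactly and conserves pixel mass", {
  p <- generate_patch(nuclei_scene_spec(image_size = 128L), 1)
  tiles <- grid_patches(p$image, 64L)
  expect_length(tiles, 4L)
  expect_equal(sum(sapply(tiles, sum)), sum(p$image))
  one <- grid_patches(p$image, 128L)
  expect_length(one, 1L)
  expect_identical(one[[1]], p$image)
  # row-major order: tile 2 is the top-right quadrant
  expect_identical(tiles[[2]], p$image[1:64, 65:128, , drop = FALSE])
  expect_error(grid_patches(p$image, 48L), "divisible")
})

test_that("random crops are aligned, in-range, and reproducible", {
  p <- generate_patch(nuclei_scene_spec(image_size = 96L), 2)
  cr1 <- random_crops(p$image, p$mask, 32L, 20L, rng = 11)
  cr2 <- random_crops(p$image, p$mask, 32L, 20L, rng = 11)
  expect_identical(lapply(cr1, `[[`, "row"), lapply(cr2, `[[`, "row"))
  expect_identical(lapply(cr1, `[[`, "col"), lapply(cr2, `[[`, "col"))
  for (cr in cr1[1:5]) {
    expect_equal(dim(cr$image), c(32L, 32L, 3L))
    expect_true(cr$row >= 0 && cr$row <= 96 - 32)
    expect_identical(cr$image,
                     p$image[cr$row + 1:32, cr$col + 1:32, , drop = FALSE])
    expect_identical(cr$mask,
                     p$mask[cr$row + 1:32, cr$col + 1:32, drop = FALSE])
  }
  full <- random_crops(p$image, p$mask, 96L, 2L, rng = 1)
  expect_identical(full[[1]]$image, p$image)
  expect_error(random_crops(p$image, p$mask, 128L, 1L), "exceeds")
})

test_that("patch extraction follows the count law W * tiles^2 * crops", {
  spec <- tiny_spec()
  d <- withr::local_tempdir()
  man <- generate_corpus(3, spec, list(stain_domain()), d, seed = 2)
  cases <- list(c(resize = 128L, grid = 64L, crop = 32L, n = 5L),
                c(resize = 128L, grid = 128L, crop = 64L, n = 7L),
                c(resize = 192L, grid = 64L, crop = 64L, n = 2L))
  for (cs in cases) {
    cfg <- patch_extraction_config(cs["resize"], cs["grid"], cs["crop"], cs["n"])
    ps <- build_training_set(man, cfg, rng = 1, out_dir = withr::local_tempdir())
    expect_equal(nrow(ps$index), 3 * (cs[["resize"]] / cs[["grid"]])^2 * cs[["n"]])
  }
  # empty manifest: empty set, no error
  empty <- data.frame(image = character(0), mask = character(0))
  ps0 <- build_training_set(empty, patch_extraction_config(128L, 64L, 32L, 5L),
                            rng = 1, out_dir = withr::local_tempdir())
  expect_equal(nrow(ps0$index), 0L)
  # missing file names the offending row
  bad <- data.frame(image = c(utils::read.csv(man)$image[1], "gone.png"),
                    mask = c(utils::read.csv(man)$mask[1], "gone.tif"))
  expect_error(build_training_set(bad, patch_extraction_config(128L, 64L, 32L, 2L),
                                  rng = 1, out_dir = withr::local_tempdir()),
               "row 2")
})

test_that("patch index is reproducible and lazy crops equal materialized ones", {
  d <- withr::local_tempdir()
  man <- generate_corpus(2, tiny_spec(), list(stain_domain()), d, seed = 3)
  cfg <- patch_extraction_config(128L, 64L, 32L, 4L)
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  ps1 <- build_training_set(man, cfg, rng = 5, out_dir = o1)
  ps2 <- build_training_set(man, cfg, rng = 5, out_dir = o2, materialize = TRUE)
  cols <- c("source_image", "tile_row", "tile_col", "crop_row", "crop_col")
  expect_identical(ps1$index[cols], ps2$index[cols])
  for (i in c(1L, 7L, 32L)) {
    lazy <- read_crop(ps1, i)
    mat <- read_crop(ps2, i)
    # materialized crops pass through 8-bit PNG quantization
    expect_lt(max(abs(lazy$image - mat$image)), 0.5 / 255 + 1e-12)
    expect_identical(lazy$mask, mat$mask)
  }
  expect_true(all(file.exists(ps2$index$crop_image)))
})

test_that("no-op augmentation config returns the input unchanged", {
  img <- random_image(32)
  cfg <- augment_config(flip_prob = 0, rot90_prob = 0, blur_prob = 0,
                        brightness_contrast_prob = 0, jitter_prob = 0)
  v <- make_contrastive_views(img, cfg, rng = 4)
  expect_identical(v$view_i, img)
  expect_identical(v$view_j, img)
})

test_that("contrastive views are reproducible and stay in [0, 1]", {
  img <- random_image(32, seed = 2)
  v1 <- make_contrastive_views(img, augment_config(), rng = 9)
  v2 <- make_contrastive_views(img, augment_config(), rng = 9)
  expect_identical(v1, v2)
  expect_true(all(v1$view_i >= 0 & v1$view_i <= 1))
  expect_true(all(v1$view_j >= 0 & v1$view_j <= 1))
  expect_equal(dim(v1$view_i), dim(img))
})

test_that("pure flips are involutions", {
  img <- random_image(16, seed = 3)
  cfg <- augment_config(flip_prob = 1, rot90_prob = 0, blur_prob = 0,
                        brightness_contrast_prob = 0, jitter_prob = 0)
  v <- make_contrastive_views(img, cfg, rng = 1)
  # flip_prob = 1 applies both mirror axes: a 180-degree involution
  expect_false(identical(v$view_i, img))
  expect_identical(v$view_i[rev(seq_len(16)), rev(seq_len(16)), ], img)
  flipped_again <- stainseg:::flip_v(stainseg:::flip_h(v$view_i))
  expect_identical(flipped_again, img)
})

test_that("geometric augmentation keeps image and mask aligned", {
  p <- generate_patch(tiny_spec(), 6)
  rng <- rng_stream(12)
  for (i in 1:10) {
    a <- augment_pair_geometric(p$image, p$mask, rng = rng)
    nuc_img <- a$image[, , 3][a$mask > 0]
    expect_lt(max(abs(nuc_img - stainseg:::NUCLEUS_BASE_RGB[3])), 0.05)
    expect_equal(sort(unique(as.vector(a$mask))), sort(unique(as.vector(p$mask))))
    expect_equal(sum(a$mask > 0), sum(p$mask > 0))
  }
})
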