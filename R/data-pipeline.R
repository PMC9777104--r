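# Image/mask I/O, the WSI-to-patch extraction scheme (resize to 1024,
# non-overlapping 512 tiles, 200 random 256 crops per tile), and stochastic
# augmented view pairs for contrastive learning.

#' Load an RGB image as an `H x W x 3` array in `[0, 1]`
#'
#' @param path PNG or TIFF file.
#' @return Numeric array `H x W x 3`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  }, error = function(e) stop("failed to read image ", path, ": ", conditionMessage(e)))
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Save an RGB image as 8-bit PNG
#'
#' Round trip through [load_image()] is bit-identical for images already on
#' the 8-bit grid.
#'
#' @param img Array `H x W x 3` in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Load an instance (or binary) mask as an integer matrix
#'
#' 16-bit TIFF masks preserve labels exactly; PNG masks are read on the
#' 8-bit grid (sufficient for binary predictions).
#'
#' @param path TIFF or PNG file.
#' @return Integer matrix, 0 = background.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("mask file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      round(tiff::readTIFF(path) * 65535)
    } else {
      round(png::readPNG(path) * 255)
    }
  }, error = function(e) stop("failed to read mask ", path, ": ", conditionMessage(e)))
  if (length(dim(m)) == 3L) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

#' Save an instance mask
#'
#' TIFF output is 16-bit unsigned (labels up to 65535, exact); PNG output
#' is 8-bit (labels up to 255, intended for binary masks).
#'
#' @param mask Integer matrix of labels.
#' @param path Output path (`.tif`/`.tiff` or `.png`).
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(mask) > 65535L) stop("labels exceed the 16-bit range")
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  } else {
    if (max(mask) > 255L) stop("labels exceed the 8-bit PNG range; use TIFF")
    png::writePNG(mask / 255, path)
  }
  invisible(path)
}

as_ebimage <- function(img) {
  EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
}

from_ebimage <- function(eb) {
  aperm(EBImage::imageData(eb), c(2, 1, 3))
}

#' Resize an image (bilinear)
#'
#' @param img Array `H x W x 3`.
#' @param target Output side in pixels (square).
#' @return Array `target x target x 3`, clipped to `[0, 1]`.
#' @export
resize_image <- function(img, target) {
  stopifnot(target >= 1)
  if (dim(img)[1] == target && dim(img)[2] == target) return(img)
  out <- from_ebimage(EBImage::resize(as_ebimage(img), w = target, h = target))
  pmin(pmax(out, 0), 1)
}

#' Resize a label mask (nearest neighbor)
#'
#' Nearest-neighbor interpolation guarantees the output label set is a
#' subset of the input's (no invented labels).
#'
#' @param mask Integer matrix.
#' @param target Output side in pixels.
#' @return Integer matrix `target x target`.
#' @export
resize_mask <- function(mask, target) {
  stopifnot(target >= 1)
  if (nrow(mask) == target && ncol(mask) == target) return(mask)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(t(mask)),
                                            w = target, h = target,
                                            filter = "none"))
  out <- t(out)
  storage.mode(out) <- "integer"
  out
}

#' Split an image into non-overlapping square tiles
#'
#' @param img Array `H x W x C` or matrix, with sides divisible by `patch`.
#' @param patch Tile side in pixels.
#' @return List of tiles in row-major order (left to right, top to bottom).
#' @export
grid_patches <- function(img, patch) {
  d <- dim(img)
  if (d[1] %% patch != 0L || d[2] %% patch != 0L) {
    stop("image sides (", d[1], "x", d[2], ") are not divisible by patch size ", patch)
  }
  tiles <- list()
  for (tr in seq_len(d[1] %/% patch)) {
    for (tc in seq_len(d[2] %/% patch)) {
      rows <- ((tr - 1L) * patch + 1L):(tr * patch)
      cols <- ((tc - 1L) * patch + 1L):(tc * patch)
      tiles[[length(tiles) + 1L]] <-
        if (length(d) == 3L) img[rows, cols, , drop = FALSE] else img[rows, cols, drop = FALSE]
    }
  }
  tiles
}

#' Paired random crops of an image and its mask
#'
#' Offsets are uniform integers over the valid positions, drawn from the
#' supplied stream; image and mask are cropped at identical offsets.
#'
#' @param img Array `H x W x 3`.
#' @param mask Integer matrix `H x W`.
#' @param crop Crop side in pixels (`<= min(H, W)`).
#' @param count Number of crops.
#' @param rng An [rng_stream()] or integer seed.
#' @return List of `list(image, mask, row, col)` with 0-based offsets.
#' @export
random_crops <- function(img, mask, crop, count, rng = 1L) {
  if (!inherits(rng, "rng_stream")) rng <- rng_stream(rng)
  d <- dim(img)
  if (crop > min(d[1], d[2])) {
    stop("crop size ", crop, " exceeds image size ", d[1], "x", d[2])
  }
  lapply(seq_len(count), function(i) {
    r0 <- rng_int(rng, 1, 0, d[1] - crop)
    c0 <- rng_int(rng, 1, 0, d[2] - crop)
    list(image = img[(r0 + 1):(r0 + crop), (c0 + 1):(c0 + crop), , drop = FALSE],
         mask = mask[(r0 + 1):(r0 + crop), (c0 + 1):(c0 + crop), drop = FALSE],
         row = r0, col = c0)
  })
}

#' Patch extraction configuration
#'
#' Defaults reproduce the published scheme: WSIs resized to 1024, cut into
#' four non-overlapping 512 tiles, 200 random 256 crops per tile.
#'
#' @param resize_to Resized WSI side (divisible by `grid_patch`).
#' @param grid_patch Tile side.
#' @param crop_size Random crop side (`<= grid_patch`).
#' @param crops_per_patch Random crops per tile.
#' @return A `patch_extraction_config` list.
#' @export
patch_extraction_config <- function(resize_to = 1024L, grid_patch = 512L,
                                    crop_size = 256L, crops_per_patch = 200L) {
  if (resize_to %% grid_patch != 0L) stop("resize_to must be divisible by grid_patch")
  if (crop_size > grid_patch) stop("crop_size must be <= grid_patch")
  structure(list(resize_to = as.integer(resize_to),
                 grid_patch = as.integer(grid_patch),
                 crop_size = as.integer(crop_size),
                 crops_per_patch = as.integer(crops_per_patch)),
            class = "patch_extraction_config")
}

read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(manifest))
  manifest
}

#' Build the training patch set from a corpus manifest
#'
#' Each source WSI is resized (bilinear image, nearest mask), cut into
#' non-overlapping tiles, and `crops_per_patch` random crops are drawn per
#' tile, yielding `W * (resize_to/grid_patch)^2 * crops_per_patch` crops in
#' total. By default crops are kept as a coordinate index over the sources
#' (every crop is a deterministic view, retrievable via [read_crop()]);
#' `materialize = TRUE` additionally writes each crop pair to disk.
#'
#' @param manifest Corpus manifest (data frame or CSV path with columns
#'   `image`, `mask`).
#' @param cfg A [patch_extraction_config()].
#' @param rng An [rng_stream()] or integer seed for the crop offsets.
#' @param out_dir Directory for the index (and crops when materialized).
#' @param materialize Write crop files to disk.
#' @return A `patch_set`: list with `index` (data frame), `dir`, `cfg`.
#' @export
build_training_set <- function(manifest, cfg = patch_extraction_config(),
                               rng = 1L, out_dir = tempfile("patchset"),
                               materialize = FALSE) {
  man <- read_manifest(manifest)
  if (!inherits(rng, "rng_stream")) rng <- rng_stream(rng)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (materialize) {
    dir.create(file.path(out_dir, "crops"), showWarnings = FALSE)
  }
  n_tiles_side <- cfg$resize_to %/% cfg$grid_patch
  rows <- list()
  for (w in seq_len(nrow(man))) {
    if (!file.exists(man$image[w]) || !file.exists(man$mask[w])) {
      stop("manifest row ", w, " names a missing file (",
           man$image[w], " / ", man$mask[w], ")")
    }
    img <- resize_image(load_image(man$image[w]), cfg$resize_to)
    msk <- resize_mask(load_mask(man$mask[w]), cfg$resize_to)
    tile_id <- 0L
    for (tr in seq_len(n_tiles_side)) {
      for (tc in seq_len(n_tiles_side)) {
        tile_id <- tile_id + 1L
        rowsel <- ((tr - 1L) * cfg$grid_patch + 1L):(tr * cfg$grid_patch)
        colsel <- ((tc - 1L) * cfg$grid_patch + 1L):(tc * cfg$grid_patch)
        for (j in seq_len(cfg$crops_per_patch)) {
          r0 <- rng_int(rng, 1, 0, cfg$grid_patch - cfg$crop_size)
          c0 <- rng_int(rng, 1, 0, cfg$grid_patch - cfg$crop_size)
          ci <- ""
          cm <- ""
          if (materialize) {
            stem <- sprintf("w%03d_t%02d_c%03d", w, tile_id, j)
            ci <- file.path(out_dir, "crops", paste0(stem, ".png"))
            cm <- file.path(out_dir, "crops", paste0(stem, ".tif"))
            rsel <- rowsel[(r0 + 1):(r0 + cfg$crop_size)]
            csel <- colsel[(c0 + 1):(c0 + cfg$crop_size)]
            save_image(img[rsel, csel, , drop = FALSE], ci)
            save_mask(msk[rsel, csel, drop = FALSE], cm)
          }
          rows[[length(rows) + 1L]] <- list(
            crop_image = ci, crop_mask = cm, source_image = man$image[w],
            tile_row = tr - 1L, tile_col = tc - 1L,
            crop_row = r0, crop_col = c0)
        }
      }
    }
  }
  index <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    data.frame(crop_image = character(0), crop_mask = character(0),
               source_image = character(0), tile_row = integer(0),
               tile_col = integer(0), crop_row = integer(0),
               crop_col = integer(0))
  }
  utils::write.csv(index, file.path(out_dir, "patch_index.csv"), row.names = FALSE)
  ps <- list(index = index, dir = out_dir, cfg = cfg,
             manifest = man, cache = new.env(parent = emptyenv()))
  class(ps) <- "patch_set"
  ps
}

#' Retrieve one crop pair from a patch set
#'
#' Materialized crops are read from disk; virtual crops are re-extracted
#' from the (cached) resized source.
#'
#' @param ps A `patch_set` from [build_training_set()].
#' @param i Row index into `ps$index`.
#' @return List with `image` and `mask`.
#' @export
read_crop <- function(ps, i) {
  row <- ps$index[i, ]
  if (nzchar(row$crop_image)) {
    return(list(image = load_image(row$crop_image), mask = load_mask(row$crop_mask)))
  }
  key <- row$source_image
  src <- ps$cache[[key]]
  if (is.null(src)) {
    mrow <- ps$manifest[ps$manifest$image == key, ][1, ]
    src <- list(image = resize_image(load_image(mrow$image), ps$cfg$resize_to),
                mask = resize_mask(load_mask(mrow$mask), ps$cfg$resize_to))
    # cache one source at a time: these are the largest buffers in the pipeline
    rm(list = ls(ps$cache), envir = ps$cache)
    ps$cache[[key]] <- src
  }
  gp <- ps$cfg$grid_patch
  cs <- ps$cfg$crop_size
  rows <- row$tile_row * gp + row$crop_row + seq_len(cs)
  cols <- row$tile_col * gp + row$crop_col + seq_len(cs)
  list(image = src$image[rows, cols, , drop = FALSE],
       mask = src$mask[rows, cols, drop = FALSE])
}

# ---- augmentation -------------------------------------------------------

#' Augmentation configuration for contrastive view pairs
#'
#' Defaults are the SimCLR-standard settings consistent with flips,
#' 90-degree rotations, blurring, random brightness/contrast with
#' probability 0.2, and color jitter.
#'
#' @param flip_prob Probability of a horizontal flip and, independently, a
#'   vertical flip.
#' @param rot90_prob Probability of a 90-degree rotation (k uniform in
#'   1..3).
#' @param blur_prob,blur_sigma_range Gaussian blur probability and sigma
#'   range in pixels.
#' @param brightness_contrast_prob,brightness_contrast_strength Random
#'   brightness/contrast probability and strength.
#' @param jitter_prob,jitter_strengths Color jitter probability and
#'   strengths (brightness, contrast, saturation, hue — hue as a fraction
#'   of the full circle).
#' @return An `augment_config` list.
#' @export
augment_config <- function(flip_prob = 0.5, rot90_prob = 0.5,
                           blur_prob = 0.5, blur_sigma_range = c(0.1, 2),
                           brightness_contrast_prob = 0.2,
                           brightness_contrast_strength = 0.2,
                           jitter_prob = 0.8,
                           jitter_strengths = c(brightness = 0.4, contrast = 0.4,
                                                saturation = 0.4, hue = 0.1)) {
  probs <- c(flip_prob, rot90_prob, blur_prob, brightness_contrast_prob, jitter_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(flip_prob = flip_prob, rot90_prob = rot90_prob,
                 blur_prob = blur_prob, blur_sigma_range = blur_sigma_range,
                 brightness_contrast_prob = brightness_contrast_prob,
                 brightness_contrast_strength = brightness_contrast_strength,
                 jitter_prob = jitter_prob, jitter_strengths = jitter_strengths),
            class = "augment_config")
}

rot90_arr <- function(x, k = 1L) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    x <- if (length(dim(x)) == 3L) {
      aperm(x, c(2, 1, 3))[rev(seq_len(dim(x)[2])), , , drop = FALSE]
    } else {
      t(x)[rev(seq_len(ncol(x))), , drop = FALSE]
    }
  }
  x
}

flip_h <- function(x) {
  if (length(dim(x)) == 3L) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  else x[, rev(seq_len(ncol(x))), drop = FALSE]
}

flip_v <- function(x) {
  if (length(dim(x)) == 3L) x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  else x[rev(seq_len(nrow(x))), , drop = FALSE]
}

geometric_draws <- function(cfg, rng) {
  list(hflip = rng_runif(rng, 1) < cfg$flip_prob,
       vflip = rng_runif(rng, 1) < cfg$flip_prob,
       rot = rng_runif(rng, 1) < cfg$rot90_prob,
       k = rng_sample(rng, 1:3, 1))
}

apply_geometric <- function(x, dr) {
  if (dr$hflip) x <- flip_h(x)
  if (dr$vflip) x <- flip_v(x)
  if (dr$rot) x <- rot90_arr(x, dr$k)
  x
}

apply_photometric <- function(img, cfg, rng) {
  if (rng_runif(rng, 1) < cfg$blur_prob) {
    sigma <- rng_runif(rng, 1, cfg$blur_sigma_range[1], cfg$blur_sigma_range[2])
    img <- from_ebimage(EBImage::gblur(as_ebimage(img), sigma = sigma))
  }
  if (rng_runif(rng, 1) < cfg$brightness_contrast_prob) {
    s <- cfg$brightness_contrast_strength
    a <- rng_runif(rng, 1, -s, s)
    b <- rng_runif(rng, 1, -s, s)
    img <- img * (1 + a) + b
  }
  if (rng_runif(rng, 1) < cfg$jitter_prob) {
    js <- cfg$jitter_strengths
    img <- img * rng_runif(rng, 1, 1 - js[["brightness"]], 1 + js[["brightness"]])
    cf <- rng_runif(rng, 1, 1 - js[["contrast"]], 1 + js[["contrast"]])
    img <- (img - mean(img)) * cf + mean(img)
    img <- pmin(pmax(img, 0), 1)
    px <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
    hsv <- grDevices::rgb2hsv(px, maxColorValue = 1)
    sat <- pmin(pmax(hsv[2, ] * rng_runif(rng, 1, 1 - js[["saturation"]],
                                          1 + js[["saturation"]]), 0), 1)
    hue <- (hsv[1, ] + rng_runif(rng, 1, -js[["hue"]], js[["hue"]])) %% 1
    rgb <- hsv_to_rgb_mat(hue, sat, hsv[3, ])
    img <- array(c(rgb[1, ], rgb[2, ], rgb[3, ]), dim(img))
  }
  pmin(pmax(img, 0), 1)
}

augment_view <- function(img, cfg, rng) {
  apply_photometric(apply_geometric(img, geometric_draws(cfg, rng)), cfg, rng)
}

#' Construct a contrastive view pair
#'
#' Two independent stochastic augmentations (flips, 90-degree rotations,
#' Gaussian blur, brightness/contrast, color jitter) of the same square
#' source patch.
#'
#' @param img Square image array `S x S x 3` in `[0, 1]`.
#' @param cfg An [augment_config()].
#' @param rng An [rng_stream()] or integer seed.
#' @return List with `view_i` and `view_j`, both `S x S x 3` in `[0, 1]`.
#' @export
make_contrastive_views <- function(img, cfg = augment_config(), rng = 1L) {
  if (!inherits(rng, "rng_stream")) rng <- rng_stream(rng)
  d <- dim(img)
  if (d[1] != d[2]) stop("contrastive views require a square input")
  list(view_i = augment_view(img, cfg, rng),
       view_j = augment_view(img, cfg, rng))
}

#' Aligned geometric augmentation of an image/mask pair
#'
#' Applies the same flip/rotation draws to both, so pixel-wise label
#' agreement is preserved.
#'
#' @param img Image array.
#' @param mask Label matrix.
#' @param cfg An [augment_config()] (only its geometric fields are used).
#' @param rng An [rng_stream()] or integer seed.
#' @return List with augmented `image` and `mask`.
#' @export
augment_pair_geometric <- function(img, mask, cfg = augment_config(), rng = 1L) {
  if (!inherits(rng, "rng_stream")) rng <- rng_stream(rng)
  dr <- geometric_draws(cfg, rng)
  list(image = apply_geometric(img, dr), mask = apply_geometric(mask, dr))
}
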