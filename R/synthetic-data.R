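# Synthetic H&E-like nuclei scenes: filled ellipses in hematoxylin purple
# over an eosin-pink background, with paired instance masks and
# parameterized stain domains emulating multi-laboratory color variation.

#' Describe a synthetic nuclei scene
#'
#' @param image_size Square image side in pixels (>= 64).
#' @param n_nuclei Number of nuclei to place (>= 0).
#' @param radius_range Min/max semi-major axis in pixels; max must stay
#'   below `image_size / 4`.
#' @param eccentricity_range Ellipse eccentricity range in `[0, 1)`.
#' @param overlap_allowed May nuclei overlap? When `FALSE`, placement uses
#'   rejection sampling (100 attempts per nucleus, then the nucleus is
#'   skipped).
#' @param background_texture_scale Amplitude of the smooth background
#'   texture (0 disables it).
#' @return A `nuclei_scene_spec` list.
#' @export
nuclei_scene_spec <- function(image_size = 64L, n_nuclei = 6L,
                              radius_range = c(5, 12),
                              eccentricity_range = c(0, 0.6),
                              overlap_allowed = TRUE,
                              background_texture_scale = 0.02) {
  spec <- structure(list(image_size = as.integer(image_size),
                         n_nuclei = as.integer(n_nuclei),
                         radius_range = as.numeric(radius_range),
                         eccentricity_range = as.numeric(eccentricity_range),
                         overlap_allowed = isTRUE(overlap_allowed),
                         background_texture_scale = background_texture_scale),
                    class = "nuclei_scene_spec")
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  if (spec$image_size < 64L) stop("image_size must be >= 64")
  if (spec$n_nuclei < 0L) stop("n_nuclei must be >= 0")
  if (length(spec$radius_range) != 2L || spec$radius_range[1] > spec$radius_range[2]) {
    stop("radius_range must be (min, max) with min <= max")
  }
  if (max(spec$radius_range) >= spec$image_size / 4) {
    stop("max radius must be < image_size / 4")
  }
  if (any(spec$eccentricity_range < 0) || any(spec$eccentricity_range >= 1)) {
    stop("eccentricity_range must lie in [0, 1)")
  }
  invisible(spec)
}

NUCLEUS_BASE_RGB <- c(0.35, 0.22, 0.55)
BACKGROUND_BASE_RGB <- c(0.92, 0.78, 0.86)

# Pixel set of a filled rotated ellipse, as an H x W logical matrix.
ellipse_pixels <- function(S, cx, cy, a, b, theta) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(S, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(S, ceiling(cx + a))
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(rep(cols - cx, each = length(rows)), length(rows), length(cols))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sel <- matrix(FALSE, S, S)
  sel[rows, cols] <- inside
  sel
}

#' Generate one synthetic H&E-like patch with its instance mask
#'
#' Nuclei are filled ellipses with random centers, radii, eccentricities
#' and orientations, painted purple over a pink textured background. The
#' image is quantized to the 8-bit grid so that a PNG round trip is
#' bit-identical. Output is a pure function of `(spec, seed)`.
#'
#' @param spec A [nuclei_scene_spec()].
#' @param seed Integer seed.
#' @return List with `image` (`S x S x 3` array in `[0, 1]`) and `mask`
#'   (`S x S` integer matrix, labels `1..k`, 0 = background).
#' @export
generate_patch <- function(spec, seed) {
  validate_scene_spec(spec)
  rng <- rng_stream(seed)
  S <- spec$image_size
  bg <- pmin(pmax(BACKGROUND_BASE_RGB + rng_runif(rng, 3, -0.03, 0.03), 0), 1)
  img <- array(rep(bg, each = S * S), c(S, S, 3))
  if (spec$background_texture_scale > 0) {
    tex <- matrix(rng_rnorm(rng, S * S), S, S)
    tex <- as.matrix(EBImage::gblur(EBImage::Image(tex), sigma = max(2, S / 32)))
    tex <- spec$background_texture_scale * tex / max(stats::sd(tex), 1e-8)
    img <- img + array(rep(tex, 3), c(S, S, 3))
  }
  mask <- matrix(0L, S, S)
  label <- 0L
  occupied <- matrix(FALSE, S, S)
  attempts_max <- if (spec$overlap_allowed) 1L else 100L
  for (i in seq_len(spec$n_nuclei)) {
    placed <- FALSE
    for (att in seq_len(attempts_max)) {
      a <- rng_runif(rng, 1, spec$radius_range[1], spec$radius_range[2])
      e <- rng_runif(rng, 1, spec$eccentricity_range[1], spec$eccentricity_range[2])
      b <- a * sqrt(1 - e^2)
      theta <- rng_runif(rng, 1, 0, pi)
      m <- ceiling(a) + 1
      cx <- rng_runif(rng, 1, m, S - m)
      cy <- rng_runif(rng, 1, m, S - m)
      sel <- ellipse_pixels(S, cx, cy, a, b, theta)
      if (!spec$overlap_allowed && any(occupied[sel])) next
      placed <- TRUE
      break
    }
    if (!placed) next
    label <- label + 1L
    occupied <- occupied | sel
    col <- pmin(pmax(NUCLEUS_BASE_RGB + rng_runif(rng, 3, -0.04, 0.04), 0), 1)
    for (c in 1:3) {
      plane <- img[, , c]
      plane[sel] <- col[c]
      img[, , c] <- plane
    }
    mask[sel] <- label
  }
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  list(image = img, mask = mask)
}

#' Describe a stain domain
#'
#' A stain domain perturbs patch colors the way scanner and staining
#' protocol differences do: separate hue shifts for hematoxylin-like
#' (purple-blue) and eosin-like (pink) pixels, global brightness and
#' contrast scaling, and additive Gaussian pixel noise.
#'
#' @param hematoxylin_hue_shift,eosin_hue_shift Hue shifts in degrees.
#' @param brightness_scale,contrast_scale Multiplicative factors (> 0).
#' @param noise_sd Additive Gaussian noise SD in intensity units.
#' @return A `stain_domain` list. The default arguments form the identity
#'   domain, which leaves any image bit-identical.
#' @export
stain_domain <- function(hematoxylin_hue_shift = 0, eosin_hue_shift = 0,
                         brightness_scale = 1, contrast_scale = 1,
                         noise_sd = 0) {
  if (brightness_scale <= 0 || contrast_scale <= 0) {
    stop("brightness_scale and contrast_scale must be > 0")
  }
  structure(list(hematoxylin_hue_shift = hematoxylin_hue_shift,
                 eosin_hue_shift = eosin_hue_shift,
                 brightness_scale = brightness_scale,
                 contrast_scale = contrast_scale,
                 noise_sd = noise_sd),
            class = "stain_domain")
}

is_identity_domain <- function(d) {
  d$hematoxylin_hue_shift == 0 && d$eosin_hue_shift == 0 &&
    d$brightness_scale == 1 && d$contrast_scale == 1 && d$noise_sd == 0
}

# Vectorized HSV -> RGB on columns (h in [0,1), s, v in [0,1]).
hsv_to_rgb_mat <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}

# Hue band treated as hematoxylin-like (purple-blue); the synthetic nucleus
# base hue is ~264 degrees, the background ~326 degrees.
HEMATOXYLIN_HUE_BAND <- c(220, 300)

#' Apply a stain domain to an image
#'
#' Hue shifts are applied per pixel according to its hue class
#' (hematoxylin-like hues in [220, 300] degrees vs everything else), then
#' brightness, contrast, and seeded Gaussian noise; the result is clipped
#' to `[0, 1]`. The identity domain returns the input unchanged.
#'
#' @param img Image array `H x W x 3` in `[0, 1]`.
#' @param domain A [stain_domain()].
#' @param seed Integer seed for the noise draw.
#' @return Image array, clipped to `[0, 1]`.
#' @export
apply_stain_domain <- function(img, domain, seed = 0L) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  if (min(img) < 0 || max(img) > 1) stop("image values must lie in [0, 1]")
  if (is_identity_domain(domain)) return(img)
  d <- dim(img)
  out <- img
  if (domain$hematoxylin_hue_shift != 0 || domain$eosin_hue_shift != 0) {
    px <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
    hsv <- grDevices::rgb2hsv(px, maxColorValue = 1)
    hue <- hsv[1, ] * 360
    hema <- hue >= HEMATOXYLIN_HUE_BAND[1] & hue <= HEMATOXYLIN_HUE_BAND[2]
    shift <- ifelse(hema, domain$hematoxylin_hue_shift, domain$eosin_hue_shift)
    rgb <- hsv_to_rgb_mat(((hue + shift) %% 360) / 360, hsv[2, ], hsv[3, ])
    out <- array(c(rgb[1, ], rgb[2, ], rgb[3, ]), d)
  }
  out <- (out * domain$brightness_scale - 0.5) * domain$contrast_scale + 0.5
  if (domain$noise_sd > 0) {
    rng <- rng_stream(seed)
    out <- out + array(rng_rnorm(rng, prod(d), sd = domain$noise_sd), d)
  }
  pmin(pmax(out, 0), 1)
}

#' Generate a corpus of synthetic patches on disk
#'
#' Writes `n_images` image/mask pairs (8-bit PNG images, 16-bit TIFF
#' instance masks), cycling through the given stain domains, plus a
#' manifest CSV with header `image,mask,domain,seed`. Re-running with the
#' same arguments reproduces byte-identical files.
#'
#' @param n_images Number of patches (>= 1).
#' @param spec A [nuclei_scene_spec()].
#' @param domains List of [stain_domain()]s cycled over images.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer run seed; each image derives its own sub-seed.
#' @return The manifest path, invisibly.
#' @export
generate_corpus <- function(n_images, spec = nuclei_scene_spec(),
                            domains = list(stain_domain()),
                            out_dir, seed = 1L) {
  if (n_images < 1) stop("n_images must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    img_seed <- derive_seed(seed, paste0("patch", i))
    patch <- generate_patch(spec, img_seed)
    di <- (i - 1L) %% length(domains)
    img <- apply_stain_domain(patch$image, domains[[di + 1L]],
                              seed = derive_seed(img_seed, "noise"))
    img_path <- file.path(out_dir, sprintf("img_%04d.png", i))
    mask_path <- file.path(out_dir, sprintf("mask_%04d.tif", i))
    save_image(img, img_path)
    save_mask(patch$mask, mask_path)
    rows[[i]] <- data.frame(image = img_path, mask = mask_path,
                            domain = di, seed = img_seed)
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}
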