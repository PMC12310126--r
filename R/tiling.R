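#' Tiling configuration
#'
#' Bundles the geometric parameters used when a slide image is partitioned
#' into non-overlapping square patches. The magnification string is carried
#' as metadata only; no rescaling is performed on plain raster images.
#'
#' @param patch_size Side length of each square patch, in pixels.
#' @param magnification Free-text label recording the acquisition scale,
#'   e.g. `"40x, 0.25 um/pixel"`.
#' @param tissue_fraction_min Minimum fraction of tissue pixels a tile must
#'   contain to be kept by [filter_tiles()]. Must lie in `[0, 1]`.
#' @return An object of class `tiling_config`.
#' @export
tiling_config <- function(patch_size = 512L,
                          magnification = "40x, 0.25 um/pixel",
                          tissue_fraction_min = 0.10) {
  patch_size <- as.integer(patch_size)
  if (is.na(patch_size) || patch_size < 1L)
    stop("`patch_size` must be a positive integer", call. = FALSE)
  if (!is.numeric(tissue_fraction_min) ||
      tissue_fraction_min < 0 || tissue_fraction_min > 1)
    stop("`tissue_fraction_min` must lie in [0, 1]", call. = FALSE)
  structure(
    list(patch_size = patch_size,
         magnification = as.character(magnification),
         tissue_fraction_min = tissue_fraction_min),
    class = "tiling_config"
  )
}

#' Partition a slide into a grid of non-overlapping patches
#'
#' Lays a regular grid of `patch_size` x `patch_size` tiles over a
#' `width` x `height` slide, starting at the top-left corner. Partial tiles
#' at the right and bottom edges are dropped, so the result covers the
#' largest patch-aligned sub-rectangle. Coordinates are 0-based and
#' half-open: tile (col, row) covers pixels `[x, x + size) x [y, y + size)`
#' with `x = col * size`, `y = row * size`.
#'
#' @param width,height Slide dimensions in pixels.
#' @param patch_size Tile side length in pixels.
#' @param slide_id Identifier stored with every tile reference.
#' @return A data frame of patch references with columns `slide_id`, `col`,
#'   `row`, `x`, `y`, `size`; one row per tile, in row-major order
#'   (left-to-right, then top-to-bottom).
#' @examples
#' tile_grid(1024, 1024, 512)
#' @export
tile_grid <- function(width, height, patch_size, slide_id = "slide") {
  for (v in list(width = width, height = height, patch_size = patch_size)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != floor(v))
      stop("`width`, `height` and `patch_size` must be positive integers",
           call. = FALSE)
  }
  ncol_tiles <- floor(width / patch_size)
  nrow_tiles <- floor(height / patch_size)
  if (ncol_tiles == 0L || nrow_tiles == 0L) {
    return(patch_refs(slide_id = character(0), col = integer(0),
                      row = integer(0), size = integer(0)))
  }
  grid <- expand.grid(col = seq_len(ncol_tiles) - 1L,
                      row = seq_len(nrow_tiles) - 1L)
  patch_refs(slide_id = slide_id, col = grid$col, row = grid$row,
             size = as.integer(patch_size))
}

#' Construct a patch-reference table
#'
#' @param slide_id Slide identifier (recycled).
#' @param col,row 0-based grid indices.
#' @param size Patch side length in pixels (recycled).
#' @return Data frame with columns `slide_id`, `col`, `row`, `x`, `y`,
#'   `size`; pixel origins satisfy `x = col * size`, `y = row * size`.
#' @export
patch_refs <- function(slide_id, col, row, size) {
  col <- as.integer(col); row <- as.integer(row); size <- as.integer(size)
  if (any(col < 0L) || any(row < 0L)) stop("grid indices must be >= 0", call. = FALSE)
  if (any(size < 1L)) stop("`size` must be positive", call. = FALSE)
  data.frame(slide_id = as.character(slide_id), col = col, row = row,
             x = col * size, y = row * size, size = size,
             stringsAsFactors = FALSE)
}

#' Detect tissue by saturation thresholding
#'
#' Computes the HSV saturation of every pixel and classifies pixels whose
#' saturation exceeds a global Otsu threshold as tissue. H&E-stained tissue
#' is strongly colored (high saturation) whereas slide background is
#' near-white/grey (saturation near zero), so a single global threshold
#' separates the two. Degenerate images with (near-)constant saturation are
#' classified by an absolute floor instead, so an all-white image yields an
#' all-background mask and a uniformly colored image an all-tissue mask.
#'
#' @param image RGB array `height x width x 3` with values in `[0, 1]`.
#' @return Logical matrix `height x width`; `TRUE` marks tissue.
#' @export
tissue_mask <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("`image` must be an RGB array (height x width x 3)", call. = FALSE)
  if (any(dim(image)[1:2] < 1L)) stop("`image` must have >= 1 pixel", call. = FALSE)
  cmax <- pmax(image[, , 1], image[, , 2], image[, , 3])
  cmin <- pmin(image[, , 1], image[, , 2], image[, , 3])
  sat <- ifelse(cmax > 0, (cmax - cmin) / cmax, 0)
  if (diff(range(sat)) < 1e-6) {
    # constant saturation: Otsu is undefined; fall back to an absolute floor
    return(matrix(sat > 0.05, nrow = nrow(sat), ncol = ncol(sat)))
  }
  thr <- EBImage::otsu(sat, range = c(0, 1))
  sat > thr
}

#' Filter tiles by tissue content
#'
#' Keeps the tiles whose fraction of tissue pixels (per the mask) meets the
#' minimum; input order is preserved. Lowering the threshold never removes
#' a previously kept tile.
#'
#' @param refs Patch-reference data frame as from [tile_grid()].
#' @param mask Logical tissue mask covering the slide (rows = y, cols = x).
#' @param tissue_fraction_min Minimum tissue fraction in `[0, 1]`.
#' @return The subset of `refs` meeting the threshold.
#' @export
filter_tiles <- function(refs, mask, tissue_fraction_min = 0.10) {
  stopifnot(is.data.frame(refs), is.matrix(mask) || is.logical(mask))
  mask <- mask * 1L
  if (nrow(refs) == 0L) return(refs)
  if (any(refs$x + refs$size > ncol(mask)) || any(refs$y + refs$size > nrow(mask)))
    stop("tile reference lies outside the mask bounds", call. = FALSE)
  frac <- vapply(seq_len(nrow(refs)), function(i) {
    r <- refs[i, ]
    mean(mask[(r$y + 1L):(r$y + r$size), (r$x + 1L):(r$x + r$size)])
  }, numeric(1))
  refs[frac >= tissue_fraction_min, , drop = FALSE]
}

#' Augmentation configuration
#'
#' Training-time patch augmentation: a random rotation with angle drawn
#' uniformly in `[-max_angle, +max_angle]` degrees, horizontal and vertical
#' flips each applied with probability `flip_prob`, and color jitter
#' (brightness, contrast, saturation, hue each perturbed by a factor drawn
#' uniformly within `jitter_amount` of neutral) applied with probability
#' `jitter_prob`. With `max_angle = 0`, `flip_prob = 0`, `jitter_prob = 0`
#' the augmentation is the identity map.
#'
#' @param max_angle Maximum absolute rotation in degrees.
#' @param flip_prob Probability of each of the two flips.
#' @param jitter_prob Probability that color jitter is applied at all.
#' @param jitter_amount Half-width of the jitter factor interval.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(max_angle = 30, flip_prob = 0.5,
                           jitter_prob = 0.25, jitter_amount = 0.2) {
  stopifnot(max_angle >= 0, flip_prob >= 0, flip_prob <= 1,
            jitter_prob >= 0, jitter_prob <= 1, jitter_amount >= 0)
  structure(list(max_angle = max_angle, flip_prob = flip_prob,
                 jitter_prob = jitter_prob, jitter_amount = jitter_amount),
            class = "augment_config")
}

#' Randomly augment a patch
#'
#' Applies, in order: rotation, horizontal flip, vertical flip, color
#' jitter, with draws governed entirely by `seed` (the global RNG state is
#' saved and restored). The output has the same dimensions as the input;
#' pixels exposed by rotation are filled white, matching slide background.
#'
#' @param patch RGB array `h x w x 3`, values in `[0, 1]`.
#' @param seed Integer seed; the same seed always yields the same output.
#' @param config An [augment_config()].
#' @return Augmented RGB array of the same shape.
#' @export
augment_patch <- function(patch, seed, config = augment_config()) {
  if (!is.array(patch) || length(dim(patch)) != 3L || dim(patch)[3] != 3L)
    stop("`patch` must be an RGB array", call. = FALSE)
  stopifnot(inherits(config, "augment_config"))
  out <- with_seed(seed, {
    p <- patch
    if (config$max_angle > 0) {
      angle <- stats::runif(1, -config$max_angle, config$max_angle)
      p <- rotate_rgb(p, angle)
    }
    if (config$flip_prob > 0 && stats::runif(1) < config$flip_prob)
      p <- p[, rev(seq_len(ncol(p))), , drop = FALSE]   # horizontal flip
    if (config$flip_prob > 0 && stats::runif(1) < config$flip_prob)
      p <- p[rev(seq_len(nrow(p))), , , drop = FALSE]   # vertical flip
    if (config$jitter_prob > 0 && stats::runif(1) < config$jitter_prob) {
      f <- stats::runif(4, -config$jitter_amount, config$jitter_amount)
      p <- jitter_brightness(p, 1 + f[1])
      p <- jitter_contrast(p, 1 + f[2])
      p <- jitter_saturation(p, 1 + f[3])
      p <- jitter_hue(p, f[4])
    }
    p
  })
  out
}

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Rotate an h x w x 3 array by `angle` degrees about its centre, preserving
# shape; exposed corners are filled white. EBImage works in (x, y) order,
# hence the aperm round-trip.
rotate_rgb <- function(patch, angle) {
  img <- EBImage::Image(aperm(patch, c(2, 1, 3)), colormode = "Color")
  rot <- EBImage::rotate(img, angle, output.dim = dim(patch)[2:1],
                         bg.col = "white")
  out <- aperm(EBImage::imageData(rot), c(2, 1, 3))
  pmin(pmax(out, 0), 1)
}

jitter_brightness <- function(p, f) pmin(pmax(p * f, 0), 1)

jitter_contrast <- function(p, f) {
  m <- mean(p)
  pmin(pmax((p - m) * f + m, 0), 1)
}

jitter_saturation <- function(p, f) {
  hsv <- rgb_to_hsv_array(p)
  hsv[, , 2] <- pmin(pmax(hsv[, , 2] * f, 0), 1)
  hsv_to_rgb_array(hsv)
}

jitter_hue <- function(p, shift) {
  hsv <- rgb_to_hsv_array(p)
  hsv[, , 1] <- (hsv[, , 1] + shift) %% 1
  hsv_to_rgb_array(hsv)
}

rgb_to_hsv_array <- function(p) {
  d <- dim(p)
  m <- rbind(as.vector(p[, , 1]), as.vector(p[, , 2]), as.vector(p[, , 3]))
  h <- grDevices::rgb2hsv(m, maxColorValue = 1)
  array(c(h[1, ], h[2, ], h[3, ]), dim = d)
}

hsv_to_rgb_array <- function(hsv) {
  d <- dim(hsv)
  h <- as.vector(hsv[, , 1]) * 6
  s <- as.vector(hsv[, , 2])
  v <- as.vector(hsv[, , 3])
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), dim = d)
}

#' Read an RGB image from PNG or TIFF
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return RGB array `height x width x 3` with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a binary mask as a single-channel PNG
#'
#' @param mask Logical or 0/1 matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow = nrow(mask)), path)
  invisible(path)
}
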