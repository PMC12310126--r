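#' Rasterize attention weights onto the tile grid
#'
#' Places each patch's attention weight into its (row, col) grid cell.
#' Cells that were never tiled (background / no tissue) are `NA`. Grid
#' dimensions span the maximum referenced row and column.
#'
#' @param result An `attention_result` from [predict.mil_model()], or a
#'   plain numeric vector of attention weights.
#' @param refs Patch-reference data frame aligned with the weights.
#' @return An object of class `heatmap_grid`: `grid` (numeric matrix, `NA`
#'   = absent), `slide_id`, `patch_size`, `normalization` (`"raw"`).
#' @export
assemble_heatmap <- function(result, refs) {
  alpha <- if (inherits(result, "attention_result")) result$alpha else result
  slide_id <- if (inherits(result, "attention_result")) result$slide_id
              else as.character(refs$slide_id[1])
  if (length(alpha) != nrow(refs))
    stop("number of attention weights must equal number of refs", call. = FALSE)
  if (anyDuplicated(refs[, c("row", "col")]))
    stop("duplicate grid cells in refs", call. = FALSE)
  R <- max(refs$row) + 1L; C <- max(refs$col) + 1L
  grid <- matrix(NA_real_, nrow = R, ncol = C)
  grid[cbind(refs$row + 1L, refs$col + 1L)] <- alpha
  structure(list(grid = grid, slide_id = slide_id,
                 patch_size = refs$size[1], normalization = "raw"),
            class = "heatmap_grid")
}

#' Min-max normalize a heatmap for display
#'
#' Maps present cells linearly onto `[0, 1]`. A constant grid maps to 0.5
#' everywhere (declared convention).
#'
#' @param hm A `heatmap_grid`.
#' @return The grid with values rescaled and `normalization = "minmax"`.
#' @export
minmax_normalize <- function(hm) {
  stopifnot(inherits(hm, "heatmap_grid"))
  v <- hm$grid[!is.na(hm$grid)]
  if (length(v) == 0L) stop("heatmap has no present cells", call. = FALSE)
  rng <- range(v)
  hm$grid <- if (diff(rng) == 0) ifelse(is.na(hm$grid), NA_real_, 0.5)
             else (hm$grid - rng[1]) / diff(rng)
  hm$normalization <- "minmax"
  hm
}

#' Top-percent attention hotspot mask
#'
#' Selects the `ceiling(q * n_present)` highest-attention tiles. Ties are
#' broken by grid position, (row, col) ascending, so the mask is
#' deterministic. Masks nest: the top 1% mask is contained in the top 5%
#' mask, which is contained in the top 10% mask.
#'
#' @param hm A `heatmap_grid`.
#' @param q Fraction in `(0, 1]` of tissue tiles to select.
#' @return An object of class `hotspot_mask`: logical `grid` (selected
#'   tiles TRUE, including `FALSE` at absent cells), `level = q`,
#'   `patch_size`, `slide_id`.
#' @export
top_percent_mask <- function(hm, q) {
  stopifnot(inherits(hm, "heatmap_grid"))
  if (!is.numeric(q) || q <= 0 || q > 1)
    stop("`q` must lie in (0, 1]", call. = FALSE)
  present <- which(!is.na(hm$grid), arr.ind = TRUE)
  vals <- hm$grid[present]
  n_sel <- ceiling(q * nrow(present))
  ord <- order(-vals, present[, 1], present[, 2])
  sel <- present[ord[seq_len(n_sel)], , drop = FALSE]
  grid <- matrix(FALSE, nrow(hm$grid), ncol(hm$grid))
  grid[sel] <- TRUE
  structure(list(grid = grid, level = q, patch_size = hm$patch_size,
                 slide_id = hm$slide_id),
            class = "hotspot_mask")
}

#' Median attention mask
#'
#' Selects the tiles whose attention is at least the median of the present
#' attention values; by construction at least half of the tissue tiles are
#' selected.
#'
#' @param hm A `heatmap_grid`.
#' @return A `hotspot_mask` with `level = "median"`.
#' @export
median_mask <- function(hm) {
  stopifnot(inherits(hm, "heatmap_grid"))
  v <- hm$grid[!is.na(hm$grid)]
  if (length(v) == 0L) stop("heatmap has no present cells", call. = FALSE)
  med <- stats::median(v)
  grid <- !is.na(hm$grid) & hm$grid >= med
  structure(list(grid = grid, level = "median", patch_size = hm$patch_size,
                 slide_id = hm$slide_id),
            class = "hotspot_mask")
}

#' Binarize an attention map at pixel resolution
#'
#' Upsamples a tile-level mask so each selected tile paints its
#' `patch_size x patch_size` pixel block with 1. The default mask is the
#' median rule (the map whose binarized version feeds the biomarker
#' overlap score); a top-percent mask can be requested via `level`.
#'
#' @param hm A `heatmap_grid`.
#' @param level `"median"` (default) or a numeric fraction for a
#'   top-percent mask.
#' @param patch_size Pixel block per tile; defaults to the grid's own.
#' @return Logical pixel matrix of size
#'   `nrow(grid)*patch_size x ncol(grid)*patch_size`.
#' @export
binarize_attention <- function(hm, level = "median", patch_size = NULL) {
  stopifnot(inherits(hm, "heatmap_grid"))
  mask <- if (identical(level, "median")) median_mask(hm)
          else top_percent_mask(hm, level)
  upsample_mask(mask, patch_size %||% hm$patch_size)
}

#' Upsample a tile-level hotspot mask to pixel resolution
#'
#' @param mask A `hotspot_mask`.
#' @param patch_size Pixels per tile side.
#' @return Logical pixel matrix.
#' @export
upsample_mask <- function(mask, patch_size = NULL) {
  stopifnot(inherits(mask, "hotspot_mask"))
  ps <- as.integer(patch_size %||% mask$patch_size)
  kronecker(mask$grid * 1L, matrix(1L, ps, ps)) > 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a heatmap as a grayscale PNG with a JSON sidecar
#'
#' The grid is min-max normalized for display; absent cells render black.
#' The sidecar records slide id, patch size, level and normalization so
#' the raster is self-describing.
#'
#' @param hm A `heatmap_grid` or `hotspot_mask`.
#' @param path Output PNG path; the sidecar is written at `<path>.json`.
#' @export
write_heatmap_png <- function(hm, path) {
  if (inherits(hm, "hotspot_mask")) {
    img <- hm$grid * 1
    meta <- list(slide_id = hm$slide_id, patch_size = hm$patch_size,
                 level = hm$level, normalization = "binary")
  } else {
    n <- minmax_normalize(hm)
    img <- ifelse(is.na(n$grid), 0, n$grid)
    meta <- list(slide_id = hm$slide_id, patch_size = hm$patch_size,
                 level = "heatmap", normalization = "minmax")
  }
  png::writePNG(img, path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
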