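#' Resample / transform a binary mask onto a target frame
#'
#' With no transform, the mask is nearest-neighbour resampled to the target
#' dimensions. An optional 3x3 affine matrix (mapping source pixel
#' coordinates to target pixel coordinates, in (row, col, 1) homogeneous
#' form) is applied by backward mapping; it must be invertible. The output
#' is strictly binary; target pixels that map outside the source are
#' background.
#'
#' @param mask Logical or 0/1 matrix.
#' @param target_dims `c(rows, cols)` of the output.
#' @param transform Optional 3x3 affine matrix (source -> target).
#' @return Logical matrix of size `target_dims`.
#' @export
align_mask <- function(mask, target_dims, transform = NULL) {
  mask <- mask > 0
  tr <- as.integer(target_dims[1]); tc <- as.integer(target_dims[2])
  if (is.null(transform)) {
    ri <- pmin(pmax(ceiling((seq_len(tr) - 0.5) * nrow(mask) / tr), 1L), nrow(mask))
    ci <- pmin(pmax(ceiling((seq_len(tc) - 0.5) * ncol(mask) / tc), 1L), ncol(mask))
    return(mask[ri, ci, drop = FALSE])
  }
  if (!is.matrix(transform) || !all(dim(transform) == c(3, 3)))
    stop("`transform` must be a 3x3 affine matrix", call. = FALSE)
  det_t <- det(transform)
  if (!is.finite(det_t) || abs(det_t) < 1e-12)
    stop("`transform` is not invertible", call. = FALSE)
  inv <- solve(transform)
  grid <- expand.grid(row = seq_len(tr), col = seq_len(tc))
  # pixel centres, backward-mapped into the source frame
  src <- inv %*% rbind(grid$row - 0.5, grid$col - 0.5, 1)
  sr <- floor(src[1, ]) + 1L
  sc <- floor(src[2, ]) + 1L
  ok <- sr >= 1L & sr <= nrow(mask) & sc >= 1L & sc <= ncol(mask)
  out <- matrix(FALSE, tr, tc)
  out[cbind(grid$row[ok], grid$col[ok])] <- mask[cbind(sr[ok], sc[ok])]
  out
}

#' Coverage overlap between attention and a biomarker mask
#'
#' The overlap statistic divides the intersection area by the biomarker
#' mask's own area, `|A intersect B| / |B|` — a coverage (recall-style)
#' score answering "what fraction of the biomarker-positive area falls
#' inside the attended region". Note this differs from the Jaccard index,
#' which divides by the union; [jaccard_index()] reports that separately.
#'
#' @param attention_mask Binarized attention raster (logical/0-1 matrix).
#' @param biomarker_mask Binary biomarker raster of identical dimensions
#'   with at least one positive pixel.
#' @return Score in `[0, 1]`.
#' @export
overlap_iou <- function(attention_mask, biomarker_mask) {
  a <- attention_mask > 0; b <- biomarker_mask > 0
  if (!all(dim(a) == dim(b)))
    stop("mask dimensions differ", call. = FALSE)
  nb <- sum(b)
  if (nb == 0L)
    stop("overlap score undefined: biomarker mask has no positive pixels",
         call. = FALSE)
  sum(a & b) / nb
}

#' Jaccard index of two binary masks
#'
#' `|A intersect B| / |A union B|`; the symmetric overlap measure, reported
#' alongside the coverage score.
#'
#' @inheritParams overlap_iou
#' @return Score in `[0, 1]` (`NaN` if both masks are empty).
#' @export
jaccard_index <- function(attention_mask, biomarker_mask) {
  a <- attention_mask > 0; b <- biomarker_mask > 0
  if (!all(dim(a) == dim(b))) stop("mask dimensions differ", call. = FALSE)
  u <- sum(a | b)
  if (u == 0L) return(NaN)
  sum(a & b) / u
}

#' Score one slide's attention against a set of biomarker masks
#'
#' @param attention_mask Binarized attention raster.
#' @param masks Named list of binary biomarker rasters (names = markers).
#' @param slide_id Slide identifier for the report rows.
#' @return Data frame: `slide_id`, `marker`, `intersection_px`, `mask_px`,
#'   `score_coverage` (the printed overlap statistic), `score_jaccard`.
#' @export
score_slide_overlap <- function(attention_mask, masks, slide_id = "slide") {
  rows <- lapply(names(masks), function(m) {
    b <- masks[[m]] > 0
    data.frame(slide_id = slide_id, marker = m,
               intersection_px = sum((attention_mask > 0) & b),
               mask_px = sum(b),
               score_coverage = overlap_iou(attention_mask, b),
               score_jaccard = jaccard_index(attention_mask, b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort-level overlap report
#'
#' Aggregates per-slide overlap scores into per-marker mean and sample
#' standard deviation, plus the overall mean across markers (the mean of
#' the per-marker means). A marker seen on a single slide reports `NA` for
#' its standard deviation.
#'
#' @param scores Data frame with columns `marker` and a score column.
#' @param score_col Which column to aggregate (default `"score_coverage"`).
#' @return An object of class `iou_report`: `per_marker` data frame
#'   (`marker`, `mean`, `sd`, `n`) and scalar `overall_mean`.
#' @export
cohort_iou_report <- function(scores, score_col = "score_coverage") {
  stopifnot(is.data.frame(scores), score_col %in% names(scores))
  markers <- unique(scores$marker)
  per <- do.call(rbind, lapply(markers, function(m) {
    v <- scores[[score_col]][scores$marker == m]
    data.frame(marker = m, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  structure(list(per_marker = per, overall_mean = mean(per$mean)),
            class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat("<iou_report> per-marker coverage of biomarker masks by attention:\n")
  print(x$per_marker, row.names = FALSE)
  cat(sprintf("overall mean: %.3f\n", x$overall_mean))
  invisible(x)
}
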