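#' Construct a feature bag
#'
#' A bag is one slide's full set of patch feature vectors together with the
#' patch references they came from and (for training) the slide-level
#' label. Row `i` of `features` always corresponds to row `i` of `refs`;
#' this ordering is what lets attention weights be mapped back onto the
#' slide grid.
#'
#' @param slide_id Slide identifier.
#' @param features Numeric `N x d` matrix of patch embeddings, all finite.
#' @param refs Patch-reference data frame with `N` rows (see [patch_refs()]),
#'   or `NULL` when geometry is unknown.
#' @param label Binary slide label (1 = pCR, 0 = non-pCR) or `NA` at
#'   inference time.
#' @param encoder Identity string of the encoder that produced `features`.
#' @return An object of class `feature_bag`.
#' @export
feature_bag <- function(slide_id, features, refs = NULL, label = NA,
                        encoder = "unknown") {
  features <- as.matrix(features)
  if (nrow(features) < 1L) stop("a bag must contain at least one patch", call. = FALSE)
  if (!all(is.finite(features))) stop("`features` must be finite", call. = FALSE)
  if (!is.null(refs)) {
    stopifnot(is.data.frame(refs))
    if (nrow(refs) != nrow(features))
      stop("`refs` must have one row per feature row", call. = FALSE)
  }
  if (!is.na(label) && !label %in% c(0, 1))
    stop("`label` must be 0, 1 or NA", call. = FALSE)
  structure(
    list(slide_id = as.character(slide_id), features = features, refs = refs,
         label = if (is.na(label)) NA else as.integer(label),
         d = ncol(features), encoder = as.character(encoder)),
    class = "feature_bag"
  )
}

#' @export
print.feature_bag <- function(x, ...) {
  cat(sprintf("<feature_bag> %s: %d patches x %d features, label = %s (%s)\n",
              x$slide_id, nrow(x$features), x$d,
              ifelse(is.na(x$label), "absent", x$label), x$encoder))
  invisible(x)
}

#' Deterministic stub patch encoder
#'
#' A drop-in test double for a pathology foundation-model encoder. The
#' patch is flattened and passed through a fixed pseudo-random Gaussian
#' projection determined solely by the target dimensionality, the seed and
#' the patch shape, scaled by `1/sqrt(n_pixels)` so outputs are of unit
#' order for inputs in `[0, 1]`. The map is linear and fully deterministic:
#' an all-zero patch encodes to the zero vector and doubling the patch
#' doubles the embedding.
#'
#' @param d Output dimensionality.
#' @param seed Seed fixing the projection.
#' @param input_size Optional required input side length; when set,
#'   [encode_patch()] rejects patches of any other size.
#' @return An encoder handle of class `mil_encoder`.
#' @export
stub_encoder <- function(d = 1536L, seed = 1L, input_size = NULL) {
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("`d` must be >= 1", call. = FALSE)
  structure(
    list(name = sprintf("stub(d=%d,seed=%d)", d, as.integer(seed)),
         d = d, seed = as.integer(seed), input_size = input_size),
    class = "mil_encoder"
  )
}

#' Encode one patch with the stub projection
#'
#' @param patch Numeric array (any shape; typically `h x w x 3` RGB).
#' @param d Output dimensionality.
#' @param seed Seed fixing the projection matrix.
#' @return Numeric vector of length `d`.
#' @export
stub_encode <- function(patch, d, seed = 1L) {
  v <- as.vector(patch)
  n <- length(v)
  # projection depends only on (d, seed, patch shape): derive a stream seed
  proj_seed <- (as.integer(seed) * 7919L + n %% 104729L) %% .Machine$integer.max
  proj <- with_seed(proj_seed, matrix(stats::rnorm(d * n), nrow = d))
  as.vector(proj %*% v) / sqrt(n)
}

#' Encode a patch through an encoder handle
#'
#' @param patch RGB array.
#' @param encoder An encoder handle, e.g. from [stub_encoder()].
#' @return Numeric feature vector of length `encoder$d`.
#' @export
encode_patch <- function(patch, encoder) {
  stopifnot(inherits(encoder, "mil_encoder"))
  if (!is.null(encoder$input_size) &&
      !all(dim(patch)[1:2] == encoder$input_size))
    stop(sprintf("patch is %dx%d but the encoder expects %dx%d",
                 dim(patch)[1], dim(patch)[2],
                 encoder$input_size, encoder$input_size), call. = FALSE)
  out <- stub_encode(patch, encoder$d, encoder$seed)
  if (length(out) != encoder$d || !all(is.finite(out)))
    stop("encoder returned an invalid vector", call. = FALSE)
  out
}

#' Encode every tile of a slide into a feature bag
#'
#' Crops each referenced tile from the slide image (or obtains it from a
#' patch-source function), encodes it, and stacks the embeddings in the
#' order of `refs`.
#'
#' @param refs Patch-reference data frame; must be non-empty.
#' @param image Either an RGB array covering all refs, or a function
#'   `function(ref_row)` returning the patch for one reference.
#' @param encoder Encoder handle.
#' @param label Optional slide label to store in the bag.
#' @param slide_id Slide identifier; defaults to the refs' slide_id.
#' @return A [feature_bag()] with `nrow(refs)` feature rows.
#' @export
encode_slide <- function(refs, image, encoder, label = NA, slide_id = NULL) {
  if (!is.data.frame(refs) || nrow(refs) == 0L)
    stop("cannot encode a slide with no tissue patches (empty bag)", call. = FALSE)
  if (is.null(slide_id)) slide_id <- refs$slide_id[1]
  get_patch <- if (is.function(image)) {
    image
  } else {
    function(r) image[(r$y + 1L):(r$y + r$size),
                      (r$x + 1L):(r$x + r$size), , drop = FALSE]
  }
  feats <- t(vapply(seq_len(nrow(refs)), function(i) {
    encode_patch(get_patch(refs[i, ]), encoder)
  }, numeric(encoder$d)))
  feature_bag(slide_id, feats, refs = refs, label = label,
              encoder = encoder$name)
}

#' Persist / restore a feature bag
#'
#' One file per slide, holding the feature matrix, the patch-reference
#' table, the label, the dimensionality and the encoder identity as a
#' keyed container. Features round-trip bit-exactly.
#'
#' @param bag A `feature_bag`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_bag <- function(bag, path) {
  stopifnot(inherits(bag, "feature_bag"))
  obj <- list(format = "milpath_bag", version = 1L,
              slide_id = bag$slide_id, features = bag$features,
              refs = bag$refs, label = bag$label, d = bag$d,
              encoder = bag$encoder)
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' @rdname write_bag
#' @export
read_bag <- function(path) {
  if (!file.exists(path)) stop("bag file not found: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt bag file: ", path, call. = FALSE))
  if (!identical(obj$format, "milpath_bag"))
    stop("not a milpath feature container: ", path, call. = FALSE)
  if (!identical(obj$d, ncol(obj$features)))
    stop("container metadata d does not match the feature matrix", call. = FALSE)
  feature_bag(obj$slide_id, obj$features, refs = obj$refs,
              label = obj$label, encoder = obj$encoder)
}
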