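#' Synthetic cohort configuration
#'
#' Defines a cohort of feature bags with a planted minority of signal
#' patches. Background patches are isotropic Gaussian noise; in positive
#' (responder) bags a `signal_fraction` of patches has its mean shifted by
#' `effect_size` along a fixed unit direction (the first feature
#' coordinate). Negative bags contain no signal patches. This is the
#' simplest distribution under which attention-MIL is learnable, and it
#' carries ground-truth patch flags so attention recovery can be measured.
#'
#' @param n_bags Number of slides/bags in the cohort.
#' @param bag_size_range Integer `c(min, max)` patches per bag.
#' @param d Feature dimensionality.
#' @param signal_fraction Fraction of signal patches in positive bags,
#'   in `(0, 1]`.
#' @param effect_size Mean shift of signal patches, in units of `noise_sd`;
#'   at 0 no patches are planted and both classes are identically
#'   distributed (the null cohort).
#' @param label_balance Probability a bag is positive.
#' @param noise_sd Per-feature standard deviation of background noise.
#' @param patch_size Pixel side length recorded in the synthetic tile
#'   references (kept small so pixel-level masks stay light).
#' @param seed Seed; the whole cohort is a deterministic function of it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_bags = 100L, bag_size_range = c(50L, 200L),
                       d = 16L, signal_fraction = 0.2, effect_size = 3,
                       label_balance = 0.5, noise_sd = 1,
                       patch_size = 32L, seed = 1L) {
  stopifnot(n_bags >= 1, length(bag_size_range) == 2,
            bag_size_range[1] >= 1, bag_size_range[1] <= bag_size_range[2],
            d >= 1, signal_fraction > 0, signal_fraction <= 1,
            effect_size >= 0, label_balance > 0, label_balance <= 1,
            noise_sd > 0, patch_size >= 1)
  structure(list(n_bags = as.integer(n_bags),
                 bag_size_range = as.integer(bag_size_range),
                 d = as.integer(d), signal_fraction = signal_fraction,
                 effect_size = effect_size, label_balance = label_balance,
                 noise_sd = noise_sd, patch_size = as.integer(patch_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic cohort of feature bags
#'
#' @param cfg A [sim_config()].
#' @return List with `bags` (list of labelled [feature_bag()]s, each with a
#'   square-ish synthetic tile grid in `refs`), `labels` (data frame
#'   `slide_id`, `patient_id`, `label`; one patient per slide), and
#'   `signal_flags` (list of logical vectors marking the planted signal
#'   patches in each bag).
#' @export
gen_bags <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    bags <- vector("list", cfg$n_bags)
    flags <- vector("list", cfg$n_bags)
    labels <- integer(cfg$n_bags)
    for (i in seq_len(cfg$n_bags)) {
      n <- sample(cfg$bag_size_range[1]:cfg$bag_size_range[2], 1L)
      y <- stats::rbinom(1L, 1L, cfg$label_balance)
      H <- matrix(stats::rnorm(n * cfg$d, sd = cfg$noise_sd), nrow = n)
      sig <- rep(FALSE, n)
      if (y == 1L && cfg$effect_size > 0) {
        n_sig <- max(1L, round(cfg$signal_fraction * n))
        sig[sample.int(n, n_sig)] <- TRUE
        H[sig, 1] <- H[sig, 1] + cfg$effect_size * cfg$noise_sd
      }
      slide <- sprintf("S%03d", i)
      ncol_tiles <- ceiling(sqrt(n))
      cells <- seq_len(n) - 1L
      refs <- patch_refs(slide_id = slide,
                         col = cells %% ncol_tiles,
                         row = cells %/% ncol_tiles,
                         size = cfg$patch_size)
      bags[[i]] <- feature_bag(slide, H, refs = refs, label = y,
                               encoder = "synthetic")
      flags[[i]] <- sig
      labels[i] <- y
    }
    ids <- vapply(bags, function(b) b$slide_id, character(1))
    list(bags = bags,
         labels = data.frame(slide_id = ids, patient_id = ids,
                             label = labels, stringsAsFactors = FALSE),
         signal_flags = flags)
  })
}

#' Render a toy slide image from a tissue layout
#'
#' Tissue tiles are painted a pink H&E-like tone with Gaussian texture
#' noise; background tiles are pure white. The returned ground-truth mask
#' matches the layout exactly, so tiling plus tissue filtering can be
#' checked against it.
#'
#' @param layout Logical matrix; `TRUE` marks tissue tiles.
#' @param seed Seed for the texture noise.
#' @param patch_size Pixels per tile side.
#' @return List with `image` (RGB array) and `mask` (logical pixel matrix).
#' @export
gen_slide_image <- function(layout, seed = 1L, patch_size = 32L) {
  stopifnot(is.matrix(layout))
  h <- nrow(layout) * patch_size; w <- ncol(layout) * patch_size
  mask <- kronecker(layout * 1L, matrix(1L, patch_size, patch_size)) > 0
  with_seed(seed, {
    base <- c(200, 120, 160) / 255   # pink H&E tone
    img <- array(1, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(base[ch], h, w) +
        matrix(stats::rnorm(h * w, sd = 0.03), h, w)
      channel <- img[, , ch]
      channel[mask] <- pmin(pmax(plane[mask], 0), 1)
      img[, , ch] <- channel
    }
    list(image = img, mask = mask)
  })
}

#' Generate biomarker masks correlated with planted signal patches
#'
#' Each marker mask covers a signal tile with probability `concordance`
#' and a background tile with probability `1 - concordance`, rendered at
#' pixel resolution on the bag's tile grid. `concordance = 1` reproduces
#' the signal tiles exactly; `concordance = 0` confines the marker to
#' background tiles.
#'
#' @param signal_flags Logical vector marking the bag's signal patches.
#' @param refs The bag's patch-reference data frame.
#' @param concordance Probability in `[0, 1]`.
#' @param seed Seed for the coverage draws.
#' @param markers Marker names; one mask per name.
#' @return Named list of logical pixel matrices, dimensioned to cover the
#'   grid spanned by `refs` at the refs' patch size.
#' @export
gen_biomarker_masks <- function(signal_flags, refs, concordance, seed = 1L,
                                markers = c("PD-L1", "CD8", "CD163")) {
  stopifnot(length(signal_flags) == nrow(refs),
            concordance >= 0, concordance <= 1)
  ps <- refs$size[1]
  R <- max(refs$row) + 1L; C <- max(refs$col) + 1L
  with_seed(seed, {
    out <- lapply(markers, function(m) {
      p_cover <- ifelse(signal_flags, concordance, 1 - concordance)
      covered <- stats::runif(length(p_cover)) < p_cover
      tile_grid_mask <- matrix(FALSE, R, C)
      tile_grid_mask[cbind(refs$row + 1L, refs$col + 1L)] <- covered
      kronecker(tile_grid_mask * 1L, matrix(1L, ps, ps)) > 0
    })
    names(out) <- markers
    out
  })
}
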