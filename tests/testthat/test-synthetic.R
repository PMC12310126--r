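test_that("cohort generation is fully seeded and structurally valid", {
  cfg <- sim_config(n_bags = 20, bag_size_range = c(10, 30), d = 8, seed = 41)
  c1 <- gen_bags(cfg)
  c2 <- gen_bags(cfg)
  expect_identical(lapply(c1$bags, `[[`, "features"),
                   lapply(c2$bags, `[[`, "features"))
  expect_identical(c1$labels, c2$labels)

  for (i in seq_along(c1$bags)) {
    b <- c1$bags[[i]]
    n <- nrow(b$features)
    expect_true(n >= 10 && n <= 30)
    expect_equal(nrow(b$refs), n)
    expect_length(c1$signal_flags[[i]], n)
    if (b$label == 0L) expect_false(any(c1$signal_flags[[i]]))
    if (b$label == 1L) expect_true(any(c1$signal_flags[[i]]))
  }
})

test_that("planted signal separates along the effect direction; null case does not", {
  cfg <- sim_config(n_bags = 40, bag_size_range = c(50, 100), d = 16,
                    signal_fraction = 0.2, effect_size = 3, seed = 42)
  cohort <- gen_bags(cfg)
  sig_proj <- unlist(lapply(seq_along(cohort$bags), function(i)
    cohort$bags[[i]]$features[cohort$signal_flags[[i]], 1]))
  bg_proj <- unlist(lapply(seq_along(cohort$bags), function(i)
    cohort$bags[[i]]$features[!cohort$signal_flags[[i]], 1]))
  tt <- t.test(sig_proj, bg_proj)
  expect_lt(tt$p.value, 1e-6)
  expect_gt(mean(sig_proj) - mean(bg_proj), 2)

  # with zero effect size the classes are identically distributed
  null <- gen_bags(sim_config(n_bags = 60, bag_size_range = c(50, 100),
                              d = 16, effect_size = 0, seed = 43))
  bag_means <- vapply(null$bags, function(b) mean(b$features[, 1]), numeric(1))
  y <- null$labels$label
  expect_gt(t.test(bag_means[y == 1], bag_means[y == 0])$p.value, 0.001)
  expect_false(any(unlist(null$signal_flags)))
})

test_that("toy slide images round-trip through tiling and tissue filtering", {
  layout <- matrix(TRUE, 2, 2)
  s <- gen_slide_image(layout, seed = 5, patch_size = 32)
  refs <- tile_grid(ncol(s$image), nrow(s$image), 32)
  kept <- filter_tiles(refs, tissue_mask(s$image), 0.1)
  expect_equal(nrow(kept), 4)

  half <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)   # left column tissue
  s2 <- gen_slide_image(half, seed = 6, patch_size = 32)
  expect_identical(s2$mask, kronecker(half * 1L, matrix(1L, 32, 32)) > 0)
  kept2 <- filter_tiles(tile_grid(64, 64, 32), tissue_mask(s2$image), 0.1)
  expect_equal(nrow(kept2), 2)
  expect_true(all(kept2$x == 0))                      # only the tissue column

  empty <- gen_slide_image(matrix(FALSE, 2, 2), seed = 7, patch_size = 32)
  expect_equal(nrow(filter_tiles(tile_grid(64, 64, 32),
                                 tissue_mask(empty$image), 0.1)), 0)
})

test_that("biomarker masks track planted signal at the set concordance", {
  cohort <- gen_bags(sim_config(n_bags = 4, bag_size_range = c(100, 100),
                                d = 4, seed = 44))
  i <- which(cohort$labels$label == 1)[1]
  bag <- cohort$bags[[i]]; sig <- cohort$signal_flags[[i]]
  ps <- bag$refs$size[1]

  # c = 1: mask is exactly the signal tiles; perfect attention scores 1
  m1 <- gen_biomarker_masks(sig, bag$refs, concordance = 1, seed = 3)
  sig_grid <- matrix(FALSE, max(bag$refs$row) + 1, max(bag$refs$col) + 1)
  sig_grid[cbind(bag$refs$row + 1, bag$refs$col + 1)] <- sig
  sig_px <- kronecker(sig_grid * 1L, matrix(1L, ps, ps)) > 0
  expect_identical(m1[["PD-L1"]], sig_px)
  expect_equal(overlap_iou(sig_px, m1[["CD8"]]), 1)

  # c = 0: marker confined to background tiles
  m0 <- gen_biomarker_masks(sig, bag$refs, concordance = 0, seed = 3)
  expect_false(any(m0[["PD-L1"]] & sig_px))

  # c = 0.5: coverage of the signal-tile mask is ~0.5 up to binomial error
  covs <- vapply(1:30, function(s) {
    m <- gen_biomarker_masks(sig, bag$refs, concordance = 0.5, seed = s,
                             markers = "M")
    overlap_iou(m[["M"]], sig_px)
  }, numeric(1))
  expect_gt(mean(covs), 0.38)
  expect_lt(mean(covs), 0.62)
})
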