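# Shared fixtures, built in code at test time.

# Small RGB test patch with reproducible content.
rand_patch <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3))
}

# Uniform-color image (values in [0,1] per channel).
flat_image <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# A tiny labelled bag with random features.
rand_bag <- function(n = 10, d = 8, label = 1L, seed = 1, slide_id = "S1") {
  set.seed(seed)
  cells <- seq_len(n) - 1L
  ncol_t <- ceiling(sqrt(n))
  feature_bag(slide_id, matrix(rnorm(n * d), n),
              refs = patch_refs(slide_id, cells %% ncol_t, cells %/% ncol_t, 16L),
              label = label)
}

# A quick separable cohort + fitted model, shared across tests that need
# a trained model at reduced problem size (40 bags, 20-50 patches, d = 8).
.small_fit_cache <- new.env(parent = emptyenv())
small_trained_fixture <- function() {
  if (!is.null(.small_fit_cache$fit)) return(.small_fit_cache$fit)
  cohort <- gen_bags(sim_config(n_bags = 40L, bag_size_range = c(20L, 50L),
                                d = 8L, seed = 21L))
  model <- train_mil(cohort$bags[1:24], cohort$bags[25:32],
                     train_config(max_epochs = 80L, patience = 80L,
                                  L = 32L, seed = 5L))
  fit <- list(cohort = cohort, model = model, test_idx = 33:40)
  .small_fit_cache$fit <- fit
  fit
}

# Full-scale synthetic study fixture (the generator's default conditions:
# 100 bags, 50-200 patches, d = 16, signal fraction 0.2, effect size 3),
# trained once and reused by the acceptance checks.
.study_cache <- new.env(parent = emptyenv())
study_fixture <- function() {
  if (!is.null(.study_cache$fit)) return(.study_cache$fit)
  cohort <- gen_bags(sim_config(seed = 11L))
  model <- train_mil(cohort$bags[1:60], cohort$bags[61:80],
                     train_config(seed = 7L))
  fit <- list(cohort = cohort, model = model, test_idx = 81:100)
  .study_cache$fit <- fit
  fit
}

# Printed per-fold cross-validation rows from the response-prediction
# study (five folds; accuracy, AUC, F1, sensitivity, specificity,
# precision), used to check fold aggregation.
published_fold_rows <- function() {
  list(
    list(accuracy = 0.83, auc = 0.88, f1 = 0.88, sensitivity = 0.89,
         specificity = 0.82, precision = 0.78),
    list(accuracy = 0.78, auc = 0.83, f1 = 0.78, sensitivity = 0.78,
         specificity = 0.78, precision = 0.78),
    list(accuracy = 0.83, auc = 0.91, f1 = 0.86, sensitivity = 0.90,
         specificity = 0.80, precision = 0.75),
    list(accuracy = 0.83, auc = 0.85, f1 = 0.88, sensitivity = 0.89,
         specificity = 0.82, precision = 0.78),
    list(accuracy = 0.83, auc = 0.81, f1 = 0.80, sensitivity = 0.78,
         specificity = 0.84, precision = 0.89)
  )
}
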