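#' Default pipeline configuration
#'
#' Nested list of every tunable the pipeline honours, with the training
#' protocol's fixed hyperparameters as defaults (learning rate 1e-4,
#' weight decay 1e-3, patience 50, up to 1024 epochs, batch size 1,
#' 512-pixel patches, 5 folds). The single top-level `seed` is fanned out
#' to per-stage seeds by fixed offsets so stages are independently
#' reproducible from one knob.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    sim = list(n_bags = 100L, bag_size_min = 50L, bag_size_max = 200L,
               d = 16L, signal_fraction = 0.2, effect_size = 3,
               label_balance = 0.5, noise_sd = 1, patch_size = 32L),
    tiling = list(patch_size = 512L, tissue_fraction_min = 0.1),
    train = list(learning_rate = 1e-4, weight_decay = 1e-3, momentum = 0.9,
                 batch_size = 1L, max_epochs = 1024L, patience = 50L,
                 L = 256L),
    eval = list(k = 5L, threshold = 0.5),
    heatmap = list(levels = c(0.10, 0.05, 0.01)),
    overlap = list(concordance = 0.9)
  )
}

#' Load and validate a YAML configuration
#'
#' Reads a YAML file, fills every unset key from [default_config()], and
#' rejects unknown keys by name — a misspelled key is an error, not a
#' silent no-op. An empty file yields the full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Validated nested configuration list.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  merge_config(defaults, user, prefix = "")
}

merge_config <- function(defaults, user, prefix) {
  if (!is.list(user)) stop("config section `", sub("\\.$", "", prefix),
                           "` must be a mapping", call. = FALSE)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0L)
    stop("unknown config key: `", prefix, bad[1], "`", call. = FALSE)
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      prefix = paste0(prefix, key, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

config_train <- function(config, seed) {
  tr <- config$train
  train_config(learning_rate = tr$learning_rate,
               weight_decay = tr$weight_decay, momentum = tr$momentum,
               batch_size = tr$batch_size, max_epochs = tr$max_epochs,
               patience = tr$patience, L = tr$L, seed = seed)
}

config_sim <- function(config, seed) {
  s <- config$sim
  sim_config(n_bags = s$n_bags,
             bag_size_range = c(s$bag_size_min, s$bag_size_max),
             d = s$d, signal_fraction = s$signal_fraction,
             effect_size = s$effect_size, label_balance = s$label_balance,
             noise_sd = s$noise_sd, patch_size = s$patch_size, seed = seed)
}
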