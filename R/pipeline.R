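#' Run the analysis pipeline
#'
#' Executes the requested stages in their canonical order
#' simulate -> train -> evaluate -> heatmap -> overlap, reading each
#' stage's inputs from `out_dir` and writing its outputs there. Partial
#' pipelines are allowed; a stage whose upstream artifact is missing stops
#' with a dependency error. A run manifest (command, configuration
#' snapshot, seed, artifact paths, package version, timestamp) is written
#' alongside the outputs; re-running with the same configuration and seed
#' reproduces all deterministic outputs byte-identically.
#'
#' Stage seeds are derived from the single configuration seed by fixed
#' offsets (simulate +1, train +2, evaluate +3, overlap +5), so each stage
#' is reproducible in isolation.
#'
#' @param stages Character vector of stages to run, any subset of
#'   `c("simulate", "train", "evaluate", "heatmap", "overlap")`.
#' @param config Configuration list from [load_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list of artifact paths written.
#' @export
run_pipeline <- function(stages, config = default_config(), out_dir) {
  canonical <- c("simulate", "train", "evaluate", "heatmap", "overlap")
  bad <- setdiff(stages, canonical)
  if (length(bad) > 0L) stop("unknown stage: ", bad[1], call. = FALSE)
  stages <- canonical[canonical %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  paths <- list()
  cohort_path <- file.path(out_dir, "cohort.rds")
  ckpt_path <- file.path(out_dir, "checkpoint.rds")

  need <- function(path, what, producer) {
    if (!file.exists(path))
      stop("dependency error: ", what, " not found at ", path,
           " (run the `", producer, "` stage first)", call. = FALSE)
  }

  for (stage in stages) {
    message("[milpath] stage: ", stage)
    if (stage == "simulate") {
      cohort <- gen_bags(config_sim(config, seed + 1L))
      saveRDS(cohort, cohort_path, version = 3)
      utils::write.csv(cohort$labels, file.path(out_dir, "labels.csv"),
                       row.names = FALSE)
      paths$cohort <- cohort_path
      paths$labels <- file.path(out_dir, "labels.csv")
    } else if (stage == "train") {
      need(cohort_path, "feature cohort", "simulate")
      cohort <- readRDS(cohort_path)
      split <- stratified_kfold(cohort$labels[, c("patient_id", "label")],
                                k = config$eval$k, seed = seed + 2L)
      fold <- split$folds[[1]]
      names(cohort$bags) <- cohort$labels$slide_id
      model <- train_mil(cohort$bags[fold$train], cohort$bags[fold$val],
                         config_train(config, seed + 2L))
      save_checkpoint(model, ckpt_path)
      utils::write.csv(model$log, file.path(out_dir, "training_log.csv"),
                       row.names = FALSE)
      paths$checkpoint <- ckpt_path
      paths$training_log <- file.path(out_dir, "training_log.csv")
    } else if (stage == "evaluate") {
      need(cohort_path, "feature cohort", "simulate")
      cohort <- readRDS(cohort_path)
      cv <- run_cross_validation(cohort$bags, cohort$labels,
                                 k = config$eval$k, seed = seed + 3L,
                                 config = config_train(config, seed + 3L),
                                 threshold = config$eval$threshold)
      fold_tab <- do.call(rbind, lapply(seq_along(cv$reports), function(f) {
        r <- cv$reports[[f]]
        data.frame(fold = f, accuracy = r$accuracy, auc = r$auc, f1 = r$f1,
                   sensitivity = r$sensitivity, specificity = r$specificity,
                   precision = r$precision)
      }))
      utils::write.csv(fold_tab, file.path(out_dir, "metrics_folds.csv"),
                       row.names = FALSE)
      utils::write.csv(cv$aggregate, file.path(out_dir, "metrics_aggregate.csv"),
                       row.names = FALSE)
      utils::write.csv(cv$predictions, file.path(out_dir, "predictions.csv"),
                       row.names = FALSE)
      saveRDS(cv, file.path(out_dir, "cv.rds"), version = 3)
      paths$metrics_folds <- file.path(out_dir, "metrics_folds.csv")
      paths$metrics_aggregate <- file.path(out_dir, "metrics_aggregate.csv")
      paths$predictions <- file.path(out_dir, "predictions.csv")
    } else if (stage == "heatmap") {
      need(cohort_path, "feature cohort", "simulate")
      need(ckpt_path, "model checkpoint", "train")
      cohort <- readRDS(cohort_path)
      model <- load_checkpoint(ckpt_path)
      bag <- cohort$bags[[1]]
      res <- predict(model, bag)
      hm <- assemble_heatmap(res, bag$refs)
      hdir <- file.path(out_dir, "heatmaps")
      dir.create(hdir, showWarnings = FALSE)
      write_heatmap_png(hm, file.path(hdir, paste0(bag$slide_id, "_attention.png")))
      write_heatmap_png(median_mask(hm),
                        file.path(hdir, paste0(bag$slide_id, "_median.png")))
      for (q in config$heatmap$levels) {
        write_heatmap_png(top_percent_mask(hm, q),
                          file.path(hdir, sprintf("%s_top%02d.png",
                                                  bag$slide_id, round(q * 100))))
      }
      paths$heatmaps <- hdir
    } else if (stage == "overlap") {
      need(cohort_path, "feature cohort", "simulate")
      need(ckpt_path, "model checkpoint", "train")
      cohort <- readRDS(cohort_path)
      model <- load_checkpoint(ckpt_path)
      pos <- which(cohort$labels$label == 1L)
      rows <- lapply(pos, function(i) {
        bag <- cohort$bags[[i]]
        hm <- assemble_heatmap(predict(model, bag), bag$refs)
        att <- binarize_attention(hm)
        masks <- gen_biomarker_masks(cohort$signal_flags[[i]], bag$refs,
                                     concordance = config$overlap$concordance,
                                     seed = seed + 5L + i)
        score_slide_overlap(att, masks, slide_id = bag$slide_id)
      })
      scores <- do.call(rbind, rows)
      report <- cohort_iou_report(scores)
      utils::write.csv(scores, file.path(out_dir, "overlap_scores.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(per_marker = report$per_marker, overall_mean = report$overall_mean),
        file.path(out_dir, "overlap_report.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA)
      paths$overlap_scores <- file.path(out_dir, "overlap_scores.csv")
    }
  }

  manifest <- list(
    command = paste("pipeline:", paste(stages, collapse = ",")),
    config = config, seed = seed,
    outputs = paths, out_dir = out_dir,
    version = as.character(utils::packageVersion("milpath")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
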