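#' Patient-level stratified k-fold split
#'
#' Patients are split into `k` folds stratified by label: within each
#' class, patients are shuffled (seeded) and dealt round-robin across
#' folds, so per-fold class counts differ from exact proportionality by
#' less than one. For fold iteration `f`, the test set is fold `f`, the
#' validation set is fold `f %% k + 1`, and the remaining folds train. All
#' of a patient's slides stay on the patient's side of every split.
#'
#' @param labels Named binary vector (names = patient ids, values 0/1), or
#'   a data frame with columns `patient_id` and `label` (one row per
#'   patient).
#' @param k Number of folds (>= 2).
#' @param seed Shuffle seed; identical seeds give identical assignments.
#' @return An object of class `fold_split`: `k`, `assignments` (named
#'   integer vector, fold index 1..k per patient), and `folds`, a list of
#'   `k` lists each holding `train`, `val`, `test` patient-id vectors.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  if (is.data.frame(labels)) {
    lab <- labels$label
    names(lab) <- labels$patient_id
    labels <- lab
  }
  if (is.null(names(labels))) stop("`labels` must be named by patient id", call. = FALSE)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < k))
    stop(sprintf("each class needs >= k members (have %d / %d, k = %d)",
                 counts[1], counts[2], k), call. = FALSE)
  assignments <- with_seed(seed, {
    a <- integer(length(labels))
    names(a) <- names(labels)
    # deal each class round-robin, carrying the fold cursor across classes
    # so total fold sizes also stay within one of each other
    cursor <- 0L
    for (cls in c(0, 1)) {
      ids <- sample(names(labels)[labels == cls])
      a[ids] <- (cursor + seq_along(ids) - 1L) %% k + 1L
      cursor <- (cursor + length(ids)) %% k
    }
    a
  })
  folds <- lapply(seq_len(k), function(f) {
    val_f <- f %% k + 1L
    list(test = names(assignments)[assignments == f],
         val = names(assignments)[assignments == val_f],
         train = names(assignments)[!assignments %in% c(f, val_f)])
  })
  structure(list(k = as.integer(k), assignments = assignments, folds = folds),
            class = "fold_split")
}

#' Confusion counts at a probability threshold
#'
#' A case is predicted positive iff its probability is greater than or
#' equal to the threshold (ties count positive).
#'
#' @param y Binary labels.
#' @param p Predicted probabilities, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_matrix <- function(y, p, threshold = 0.5) {
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (length(y) != length(p)) stop("`y` and `p` lengths differ", call. = FALSE)
  pred <- as.integer(p >= threshold)
  c(TP = sum(pred == 1L & y == 1), TN = sum(pred == 0L & y == 0),
    FP = sum(pred == 1L & y == 0), FN = sum(pred == 0L & y == 1))
}

#' The reported metric panel
#'
#' Accuracy, AUC, F1, sensitivity (= recall), specificity and precision,
#' computed from the confusion counts at the given threshold plus the
#' threshold-free rank AUC. A metric whose denominator is zero is reported
#' as `NaN` with a warning, never silently as 0.
#'
#' @param y Binary labels.
#' @param p Predicted probabilities.
#' @param threshold Decision threshold for the count-based metrics.
#' @return An object of class `metrics_report` (a named list): `accuracy`,
#'   `auc`, `f1`, `sensitivity`, `specificity`, `precision` and the
#'   `confusion` counts.
#' @export
compute_metrics <- function(y, p, threshold = 0.5) {
  cm <- confusion_matrix(y, p, threshold)
  metrics_from_confusion(cm, auc = if (length(unique(y)) == 2L) auc_roc(y, p) else {
    warning("AUC undefined: only one class present"); NaN
  })
}

#' Metric panel from explicit confusion counts
#'
#' @param cm Named vector/list with `TP`, `TN`, `FP`, `FN`.
#' @param auc Optional AUC to carry in the report (`NA` if unavailable).
#' @return A `metrics_report`.
#' @export
metrics_from_confusion <- function(cm, auc = NA_real_) {
  tp <- cm[["TP"]]; tn <- cm[["TN"]]; fp <- cm[["FP"]]; fn <- cm[["FN"]]
  if (tp + tn + fp + fn < 1) stop("confusion counts sum to zero", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); NaN }
    else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  sensitivity <- safe_div(tp, tp + fn, "sensitivity")
  f1 <- if (is.nan(precision) || is.nan(sensitivity) ||
            (precision + sensitivity) == 0) {
    warning("F1 undefined"); NaN
  } else 2 * precision * sensitivity / (precision + sensitivity)
  structure(list(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    auc = auc,
    f1 = f1,
    sensitivity = sensitivity,
    specificity = safe_div(tn, tn + fp, "specificity"),
    precision = precision,
    confusion = c(TP = tp, TN = tn, FP = fp, FN = fn)
  ), class = "metrics_report")
}

#' Area under the ROC curve
#'
#' The Mann-Whitney concordance probability: the chance a random positive
#' case scores above a random negative case, with ties counted 1/2.
#' Computed from midranks, which is exactly the pairwise definition.
#'
#' @param y Binary labels with both classes present.
#' @param p Scores/probabilities.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(y, p) {
  if (length(y) != length(p)) stop("`y` and `p` lengths differ", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Aggregate per-fold metric reports
#'
#' @param reports List of at least two `metrics_report`s (or named lists of
#'   metric values).
#' @return Data frame with one row per metric: `metric`, `mean`, `sd`
#'   (sample standard deviation, n-1 denominator), plus `mean_2dp` and
#'   `sd_2dp` rounded to two decimals for display.
#' @export
aggregate_folds <- function(reports) {
  if (length(reports) < 2L) stop("need at least two fold reports", call. = FALSE)
  metrics <- c("accuracy", "auc", "f1", "sensitivity", "specificity", "precision")
  metrics <- metrics[metrics %in% names(reports[[1]])]
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports, function(r) as.numeric(r[[m]]), numeric(1))
    data.frame(metric = m, mean = mean(v), sd = stats::sd(v))
  })
  out <- do.call(rbind, rows)
  out$mean_2dp <- round(out$mean, 2)
  out$sd_2dp <- round(out$sd, 2)
  out
}

#' Patient-stratified cross-validated evaluation
#'
#' Runs the full protocol: stratified k-fold split at the patient level,
#' per-fold training with early stopping on the fold's validation split,
#' prediction on the held-out test patients, and fold-level metric reports
#' aggregated as mean and standard deviation.
#'
#' @param bags List of labelled [feature_bag()]s.
#' @param slide_table Data frame mapping slides to patients: columns
#'   `slide_id`, `patient_id`, `label`. Defaults to one patient per slide.
#' @param k Number of folds.
#' @param seed Seed for the split (training uses `config$seed` offset per
#'   fold so folds are independent but reproducible).
#' @param config A [train_config()].
#' @param threshold Decision threshold for count-based metrics.
#' @return List with `split`, per-fold `reports`, per-fold `predictions`
#'   (data frame: slide, label, probability, fold), and the `aggregate`
#'   table.
#' @export
run_cross_validation <- function(bags, slide_table = NULL, k = 5L, seed = 1L,
                                 config = train_config(), threshold = 0.5) {
  if (is.null(slide_table)) {
    slide_table <- data.frame(
      slide_id = vapply(bags, function(b) b$slide_id, character(1)),
      patient_id = vapply(bags, function(b) b$slide_id, character(1)),
      label = vapply(bags, function(b) b$label, integer(1)),
      stringsAsFactors = FALSE)
  }
  names(bags) <- vapply(bags, function(b) b$slide_id, character(1))
  patient_labels <- tapply(slide_table$label, slide_table$patient_id, max)
  split <- stratified_kfold(patient_labels, k = k, seed = seed)
  reports <- vector("list", k)
  pred_rows <- list()
  for (f in seq_len(k)) {
    fold <- split$folds[[f]]
    pick <- function(pats) bags[slide_table$slide_id[
      slide_table$patient_id %in% pats]]
    cfg <- config
    cfg$seed <- config$seed + f - 1L
    model <- train_mil(pick(fold$train), pick(fold$val), cfg)
    test_bags <- pick(fold$test)
    p <- vapply(test_bags, function(b) predict(model, b)$p, numeric(1))
    y <- vapply(test_bags, function(b) b$label, integer(1))
    reports[[f]] <- compute_metrics(y, p, threshold)
    pred_rows[[f]] <- data.frame(slide_id = names(test_bags), label = y,
                                 probability = p, fold = f,
                                 row.names = NULL, stringsAsFactors = FALSE)
  }
  list(split = split, reports = reports,
       predictions = do.call(rbind, pred_rows),
       aggregate = aggregate_folds(reports))
}
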