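# Evaluation: stratified k-fold cross-validation over subjects, bilateral
# decision fusion, and diagnostic-test metrics. Group 1 (osteopenic/
# osteoporotic) is the positive class throughout.

FUSION_SCHEMES <- c("keep_left", "keep_right", "keep_osteo", "keep_healthy")

#' Stratified partition of subjects into k validation subsets
#'
#' Each class is shuffled under the seed and dealt round-robin across the
#' subsets with a cursor that continues from one class to the next, so that
#' subset sizes differ by at most 1 and per-subset class counts stay within
#' 1 of exact proportionality. With the study's 27/40 cohort and k = 7 this
#' yields subsets of 9 or 10 subjects.
#'
#' @param labels Class label per subject.
#' @param k Number of subsets (default 7).
#' @param seed RNG seed for the within-class shuffles.
#' @param ids Optional subject ids naming the membership (default
#'   `names(labels)`, else indices as character).
#' @return An `rf_folds` object: `k`, `seed`, and `membership`, a named
#'   integer vector mapping every subject id onto `1..k`.
#' @export
stratified_partition <- function(labels, k = 7L, seed = 1L, ids = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 1L || k > n) stop_wristrf("k must lie in 1..%d (got %d)", n, k)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop_wristrf("stratification requires both classes to be present")
  }
  ids <- ids %||% names(labels) %||% as.character(seq_len(n))
  if (anyDuplicated(ids)) stop_wristrf("subject ids must be unique")
  membership <- stats::setNames(integer(n), ids)
  with_seed(seed, {
    cursor <- 0L
    for (cl in classes) {
      members <- which(labels == cl)
      members <- members[sample.int(length(members))]
      slots <- (cursor + seq_along(members) - 1L) %% k + 1L
      membership[members] <- slots
      cursor <- cursor + length(members)
    }
  })
  structure(list(k = k, seed = as.integer(seed), membership = membership),
            class = "rf_folds")
}

#' Fuse the two per-arm classifications of one subject
#'
#' When both arms agree, the shared label is the diagnosis regardless of
#' scheme. On a conflict: `keep_left`/`keep_right` keep that arm's result;
#' `keep_osteo` calls the subject group 1; `keep_healthy` calls the subject
#' group 2.
#'
#' @param left_label,right_label Per-arm predicted labels
#'   (`"group1_osteo"` / `"group2_healthy"`).
#' @param scheme One of `"keep_left"`, `"keep_right"`, `"keep_osteo"`,
#'   `"keep_healthy"`. (`"separate"` bypasses fusion and is rejected here.)
#' @return The fused label.
#' @export
fuse_arm_predictions <- function(left_label, right_label, scheme) {
  if (identical(scheme, "separate")) {
    stop_wristrf("'separate' reports per-arm statistics and never reaches fusion")
  }
  scheme <- match.arg(scheme, FUSION_SCHEMES)
  valid <- c(POSITIVE_CLASS, NEGATIVE_CLASS)
  if (!(left_label %in% valid) || !(right_label %in% valid)) {
    stop_wristrf("labels must be '%s' or '%s'", POSITIVE_CLASS, NEGATIVE_CLASS)
  }
  if (left_label == right_label) return(left_label)
  switch(scheme,
         keep_left = left_label,
         keep_right = right_label,
         keep_osteo = POSITIVE_CLASS,
         keep_healthy = NEGATIVE_CLASS)
}

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth Label vectors of equal length.
#' @param positive Positive-class label (default `"group1_osteo"`).
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(predicted, truth, positive = POSITIVE_CLASS) {
  if (length(predicted) != length(truth)) {
    stop_wristrf("predicted and truth differ in length")
  }
  pos <- truth == positive
  pred_pos <- predicted == positive
  structure(list(tp = sum(pos & pred_pos), fp = sum(!pos & pred_pos),
                 tn = sum(!pos & !pred_pos), fn = sum(pos & !pred_pos)),
            class = "confusion_counts")
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy, and
#' Youden's J (`sensitivity + specificity - 1`). An empty denominator makes
#' the affected metric `NA` with a warning rather than silently 0.
#'
#' @param counts A [confusion_counts()] object; alternatively give the four
#'   tallies via `tp`, `fp`, `tn`, `fn`.
#' @param tp,fp,tn,fn Counts when given separately.
#' @return A list with `sensitivity`, `specificity`, `accuracy`, `youden_j`.
#' @examples
#' compute_metrics(tp = 83, fp = 6, tn = 94, fn = 17)
#' @export
compute_metrics <- function(counts = NULL, tp = NULL, fp = NULL, tn = NULL,
                            fn = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    if (is.null(tp)) stop_wristrf("give a confusion_counts object or all four tallies")
    counts <- structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
                        class = "confusion_counts")
  }
  with(counts, {
    if (any(c(tp, fp, tn, fn) < 0)) stop_wristrf("counts must be >= 0")
    sens <- if (tp + fn > 0) tp / (tp + fn) else {
      warning("no positives: sensitivity undefined", call. = FALSE); NA_real_
    }
    spec <- if (tn + fp > 0) tn / (tn + fp) else {
      warning("no negatives: specificity undefined", call. = FALSE); NA_real_
    }
    total <- tp + fp + tn + fn
    acc <- if (total > 0) (tp + tn) / total else {
      warning("no instances: accuracy undefined", call. = FALSE); NA_real_
    }
    list(sensitivity = sens, specificity = spec, accuracy = acc,
         youden_j = sens + spec - 1)
  })
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Subjects (never single arms) are partitioned with
#' [stratified_partition()]; for each fold a fresh classifier is built and
#' trained on the features of the training subjects only and applied to the
#' validation subjects. In `"separate"` arm mode both arms are classified
#' independently (each arm inherits its subject's true group), per-arm
#' statistics are reported under scheme `"separate"`, and the four fusion
#' schemes are additionally evaluated at subject level. Other arm modes
#' yield a single scheme block named after the mode.
#'
#' @param cohort An [rf_cohort()] containing both groups.
#' @param recipe A [feature_recipe()].
#' @param k Number of folds (default 7).
#' @param seed Seed controlling the partition and (offset per fold) each
#'   fold's classifier stream.
#' @param classifier Named list of [mlp_config()] overrides (e.g.
#'   `list(epochs = 200)`); `n_in` and `seed` are supplied internally.
#' @param schemes Fusion schemes to evaluate in `"separate"` mode.
#' @return An `rf_cv_result`: `folds` (the partition), `schemes` — a named
#'   list where each element has `per_fold` (data.frame of counts and
#'   metrics) and `mean` (fold-mean sensitivity/specificity/accuracy/
#'   youden_j) — and a config echo. Fold means drop `NA` fold metrics with a
#'   warning.
#' @export
run_cv <- function(cohort, recipe, k = 7L, seed = 1L, classifier = list(),
                   schemes = FUSION_SCHEMES) {
  if (!inherits(cohort, "rf_cohort")) stop_wristrf("not an rf_cohort")
  if (!inherits(recipe, "feature_recipe")) stop_wristrf("not a feature_recipe")
  if (length(schemes) > 0) {
    schemes <- match.arg(schemes, FUSION_SCHEMES, several.ok = TRUE)
  }
  ids <- cohort_ids(cohort)
  groups <- stats::setNames(cohort_groups(cohort), ids)
  if (length(setdiff(c(POSITIVE_CLASS, NEGATIVE_CLASS), unique(groups))) > 0) {
    stop_wristrf("cohort must contain both groups")
  }
  folds <- stratified_partition(groups, k = k, seed = seed, ids = ids)
  scheme_names <- if (recipe$arm_mode == "separate") c("separate", schemes)
                  else recipe$arm_mode
  fold_counts <- lapply(stats::setNames(nm = scheme_names), function(s) list())

  for (fold in seq_len(folds$k)) {
    val_ids <- names(folds$membership)[folds$membership == fold]
    train_ids <- setdiff(ids, val_ids)
    stopifnot(length(intersect(train_ids, val_ids)) == 0L)  # leakage guard
    if (length(unique(groups[train_ids])) < 2L) {
      stop_wristrf("fold %d has single-class training data; use a different seed",
                   fold)
    }
    sub <- function(keep) {
      rf_cohort(cohort$subjects[ids %in% keep], cohort$provenance)
    }
    train <- assemble_cohort(sub(train_ids), recipe)
    val <- assemble_cohort(sub(val_ids), recipe)
    cfg_args <- utils::modifyList(
      list(n_in = ncol(train$x), seed = seed * 100L + fold),
      classifier)
    cfg <- do.call(mlp_config, cfg_args)
    model <- mlp_train(train$x, train$y, cfg)
    pred <- predict(model, val$x)

    if (recipe$arm_mode == "separate") {
      fold_counts[["separate"]][[fold]] <-
        confusion_counts(pred$label, val$y)
      subj_truth <- stats::setNames(groups[val_ids], val_ids)
      left <- stats::setNames(pred$label[val$arm_tag == "left"],
                              val$subject_id[val$arm_tag == "left"])
      right <- stats::setNames(pred$label[val$arm_tag == "right"],
                               val$subject_id[val$arm_tag == "right"])
      for (s in schemes) {
        fused <- vapply(val_ids, function(id) {
          fuse_arm_predictions(left[[id]], right[[id]], s)
        }, character(1))
        fold_counts[[s]][[fold]] <- confusion_counts(fused, subj_truth)
      }
    } else {
      fold_counts[[recipe$arm_mode]][[fold]] <-
        confusion_counts(pred$label, val$y)
    }
  }

  result_schemes <- lapply(fold_counts, function(counts) {
    per_fold <- do.call(rbind, lapply(seq_along(counts), function(i) {
      cc <- counts[[i]]
      m <- compute_metrics(cc)
      data.frame(fold = i, tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 accuracy = m$accuracy, youden_j = m$youden_j)
    }))
    mean_of <- function(v) {
      if (anyNA(v)) {
        warning("undefined fold metric(s) excluded from the mean", call. = FALSE)
      }
      mean(v, na.rm = TRUE)
    }
    list(per_fold = per_fold,
         mean = list(sensitivity = mean_of(per_fold$sensitivity),
                     specificity = mean_of(per_fold$specificity),
                     accuracy = mean_of(per_fold$accuracy),
                     youden_j = mean_of(per_fold$youden_j)))
  })

  structure(list(folds = folds, schemes = result_schemes,
                 config = list(recipe = unclass(recipe), k = folds$k,
                               seed = as.integer(seed),
                               classifier = classifier)),
            class = "rf_cv_result")
}

#' Tabulate a cross-validation result
#'
#' @param result An `rf_cv_result`.
#' @return A data.frame with one row per scheme: fold-mean sensitivity,
#'   specificity, accuracy, and Youden's J.
#' @export
results_table <- function(result) {
  if (!inherits(result, "rf_cv_result")) stop_wristrf("not an rf_cv_result")
  do.call(rbind, lapply(names(result$schemes), function(s) {
    m <- result$schemes[[s]]$mean
    data.frame(scheme = s, sensitivity = m$sensitivity,
               specificity = m$specificity, accuracy = m$accuracy,
               youden_j = m$youden_j)
  }))
}

#' @export
print.rf_cv_result <- function(x, ...) {
  cat(sprintf("<rf_cv_result> %d-fold stratified CV, seed %d\n",
              x$folds$k, x$folds$seed))
  tab <- results_table(x)
  tab[-1] <- lapply(tab[-1], round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Bar chart of fold-mean metrics per fusion scheme
#'
#' @param x An `rf_cv_result`.
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot.rf_cv_result <- function(x, ...) {
  tab <- results_table(x)
  m <- t(as.matrix(tab[, c("sensitivity", "specificity", "accuracy")]))
  colnames(m) <- tab$scheme
  mids <- graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                            legend.text = rownames(m),
                            ylab = "fold-mean rate",
                            args.legend = list(x = "bottomright", bty = "n"),
                            ...)
  invisible(mids)
}
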