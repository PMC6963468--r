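#' Confusion counts
#'
#' Tallies TP/TN/FP/FN with abnormal (label 1) as the positive class.
#'
#' @param truth,pred Binary vectors (0 = normal, 1 = abnormal).
#' @return Named list of the four counts.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- assert_labels(truth); pred <- assert_labels(pred)
  stopifnot(length(truth) == length(pred))
  list(TP = sum(truth == 1 & pred == 1),
       TN = sum(truth == 0 & pred == 0),
       FP = sum(truth == 0 & pred == 1),
       FN = sum(truth == 1 & pred == 0))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP + TN) / n`, sensitivity (recall) `TP / (TP + FN)`,
#' specificity `TN / (TN + FP)`, precision `TP / (TP + FP)`, and F1
#' `2 * precision * recall / (precision + recall)`. A metric whose
#' denominator is zero is reported as 0 and named in the `undefined`
#' attribute column rather than raising an error, so pooled cross-validation
#' never crashes on a degenerate fold.
#'
#' @param counts List or vector with `TP`, `TN`, `FP`, `FN`.
#' @return One-row tibble with the five metrics, the four counts, and an
#'   `undefined` list-column naming any zero-denominator metrics.
#' @export
metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  n <- tp + tn + fp + fn
  if (n < 1) stop("empty evaluation: no counted instances", call. = FALSE)
  undef <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); 0 } else num / den
  }
  acc <- (tp + tn) / n
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- if (prec + sens == 0) { undef <- c(undef, "f1"); 0 } else {
    2 * prec * sens / (prec + sens)
  }
  tibble::tibble(accuracy = acc, sensitivity = sens, specificity = spec,
                 precision = prec, f1 = f1,
                 TP = tp, TN = tn, FP = fp, FN = fn,
                 undefined = list(undef))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability `P(score_pos > score_neg) +
#' 0.5 * P(tie)` via midranks, which equals the trapezoidal area under the
#' ROC curve and is invariant under any strictly increasing transform of the
#' scores.
#'
#' @param scores Positive-class scores or probabilities.
#' @param truth Binary labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- assert_labels(truth)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)                      # midranks handle ties
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Emits (FPR, TPR) pairs at every distinct score threshold, from the
#' all-positive to the all-negative operating point.
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, truth) {
  truth <- assert_labels(truth)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  purrr::map_dfr(thr, function(t) {
    pred <- as.integer(scores >= t)
    tibble::tibble(
      threshold = t,
      fpr = sum(pred == 1 & truth == 0) / max(1, sum(truth == 0)),
      tpr = sum(pred == 1 & truth == 1) / max(1, sum(truth == 1)))
  })
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into `folds` stratified folds (each class shuffled under
#' `seed` and dealt round-robin, so five folds give the 80-20 train-test
#' ratio), fits the model on each training split, predicts the held-out
#' fold, and reports both pooled metrics (from the summed confusion counts)
#' and per-fold metrics, plus the pooled AUC over held-out scores.
#'
#' @param data Data frame with numeric features and a binary label column.
#' @param fit Fitting function `function(train_data) -> fitted model`, e.g.
#'   `function(d) knn_fit(d)`.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @param label_col Name of the label column.
#' @return An `eval_report`: pooled `metrics`, `auc`, `per_fold` tibble,
#'   pooled `confusion`, held-out `scores`/`truth`/`fold_id`.
#' @export
cross_validate <- function(data, fit, folds = 5, seed = 1L,
                           label_col = "label") {
  data <- as.data.frame(data)
  y <- assert_labels(data[[label_col]])
  fold_id <- stratified_folds(y, folds, seed)
  scores <- numeric(length(y)); preds <- integer(length(y))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    model <- fit(data[!test, , drop = FALSE])
    scores[test] <- predict(model, data[test, , drop = FALSE], type = "prob")$p1
    preds[test] <- predict(model, data[test, , drop = FALSE], type = "class")
    per_fold[[f]] <- dplyr::mutate(
      metrics(confusion_counts(y[test], preds[test])), fold = f,
      .before = 1)
  }
  pooled <- metrics(confusion_counts(y, preds))
  structure(
    list(metrics = pooled,
         auc = roc_auc(scores, y),
         per_fold = dplyr::bind_rows(per_fold),
         confusion = confusion_counts(y, preds),
         scores = scores, truth = y, fold_id = fold_id,
         folds = folds, seed = seed),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<eval_report> %d-fold CV: accuracy %.3f, sensitivity %.3f, specificity %.3f, precision %.3f, F1 %.3f, AUC %.3f\n",
    x$folds, m$accuracy, m$sensitivity, m$specificity, m$precision, m$f1, x$auc))
  invisible(x)
}

#' Nested cross-validated hyperparameter selection
#'
#' For each outer training split, every candidate is scored by inner
#' cross-validated accuracy; the winning candidate is refitted on the whole
#' outer training split and evaluated on the outer test fold. This keeps the
#' outer estimate unbiased by the selection. Reports pooled outer metrics,
#' AUC, and the per-outer-fold choices.
#'
#' @param data Data frame with numeric features and a binary label column.
#' @param fit_factory `function(candidate) -> function(train_data) -> model`.
#' @param candidates List/vector of candidate parameter values (>= 1).
#' @param outer,inner Fold counts (default 5 and 5).
#' @param seed Integer seed.
#' @param label_col Name of the label column.
#' @return An `eval_report` with an extra `choices` tibble
#'   (`fold`, `candidate`, `inner_accuracy`).
#' @export
nested_select <- function(data, fit_factory, candidates, outer = 5, inner = 5,
                          seed = 1L, label_col = "label") {
  stopifnot(length(candidates) >= 1)
  data <- as.data.frame(data)
  y <- assert_labels(data[[label_col]])
  fold_id <- stratified_folds(y, outer, seed)
  scores <- numeric(length(y)); preds <- integer(length(y))
  choices <- vector("list", outer)
  for (f in seq_len(outer)) {
    test <- fold_id == f
    train <- data[!test, , drop = FALSE]
    inner_acc <- vapply(seq_along(candidates), function(ci) {
      cv <- cross_validate(train, fit_factory(candidates[[ci]]), folds = inner,
                           seed = derive_seed(seed, f * 17 + ci),
                           label_col = label_col)
      cv$metrics$accuracy
    }, numeric(1))
    best <- which.max(inner_acc)            # first max: lowest candidate index
    model <- fit_factory(candidates[[best]])(train)
    scores[test] <- predict(model, data[test, , drop = FALSE], type = "prob")$p1
    preds[test] <- predict(model, data[test, , drop = FALSE], type = "class")
    choices[[f]] <- tibble::tibble(fold = f,
                                   candidate = list(candidates[[best]]),
                                   inner_accuracy = inner_acc[best])
  }
  per_fold <- purrr::map_dfr(seq_len(outer), function(f) {
    dplyr::mutate(metrics(confusion_counts(y[fold_id == f], preds[fold_id == f])),
                  fold = f, .before = 1)
  })
  out <- structure(
    list(metrics = metrics(confusion_counts(y, preds)),
         auc = roc_auc(scores, y),
         per_fold = per_fold,
         confusion = confusion_counts(y, preds),
         scores = scores, truth = y, fold_id = fold_id,
         folds = outer, seed = seed,
         choices = dplyr::bind_rows(choices)),
    class = "eval_report")
  out
}
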