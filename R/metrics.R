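# Classification metrics: confusion matrix, recall/precision/F1/accuracy,
# ROC/AUC.  Positive class is "recurrent" throughout.

#' Confusion matrix from predictions and truth
#'
#' @param predicted,truth vectors of labels
#'   (`"recurrent"`/`"non_recurrent"` or 1/0).
#' @return named numeric vector with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(predicted, truth) {
  p <- labels_to_binary(predicted)
  y <- labels_to_binary(truth)
  c(
    tp = sum(p == 1 & y == 1),
    fp = sum(p == 1 & y == 0),
    fn = sum(p == 0 & y == 1),
    tn = sum(p == 0 & y == 0)
  )
}

#' Metrics from a confusion matrix
#'
#' Recall `TP/(TP+FN)`, precision `TP/(TP+FP)`, their harmonic-mean F1, and
#' accuracy `(TP+TN)/total`.  Undefined 0/0 ratios are reported as 0 with
#' `degenerate = TRUE` and a warning.
#'
#' @param confusion named vector or list with `tp`, `fp`, `fn`, `tn`
#'   (non-negative counts, total > 0).
#' @return list with `recall`, `precision`, `f1`, `accuracy`,
#'   `specificity`, `degenerate`.
#' @export
confusion_metrics <- function(confusion) {
  cm <- unlist(confusion)[c("tp", "fp", "fn", "tn")]
  if (any(is.na(cm))) stop("confusion matrix needs tp, fp, fn, tn")
  if (any(cm < 0)) stop("negative counts in confusion matrix")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  degenerate <- FALSE
  ratio <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      0
    } else {
      num / den
    }
  }
  recall <- ratio(cm["tp"], cm["tp"] + cm["fn"])
  precision <- ratio(cm["tp"], cm["tp"] + cm["fp"])
  f1 <- if (recall + precision == 0) {
    degenerate <- TRUE
    0
  } else {
    2 * recall * precision / (recall + precision)
  }
  specificity <- ratio(cm["tn"], cm["tn"] + cm["fp"])
  if (degenerate) warning("0/0 ratio in confusion metrics, reported as 0")
  list(
    recall = unname(recall), precision = unname(precision), f1 = unname(f1),
    accuracy = unname((cm["tp"] + cm["tn"]) / total),
    specificity = unname(specificity), degenerate = degenerate
  )
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds, returns the ROC points and the area by
#' trapezoidal integration — numerically identical to the tie-corrected
#' Mann-Whitney rank statistic.
#'
#' @param scores numeric probabilities or scores (higher = more positive).
#' @param labels vector of truth labels (both classes required).
#' @return list with `auc` and `roc_points` (data.frame `fpr`, `tpr`,
#'   monotone nondecreasing in both coordinates).
#' @export
roc_auc <- function(scores, labels) {
  y <- labels_to_binary(labels)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve")
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  # step only at distinct score values so ties share one point
  keep <- c(ss[-length(ss)] != ss[-1], TRUE)
  tpr <- c(0, cumsum(ys)[keep] / n_pos)
  fpr <- c(0, cumsum(1 - ys)[keep] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc, roc_points = data.frame(fpr = fpr, tpr = tpr))
}

#' Evaluate a classifier on a labeled tile set
#'
#' Computes per-tile probabilities, thresholds them at `threshold` for the
#' confusion matrix, and reports the full metric suite.
#'
#' @param model a trained `tile_classifier`.
#' @param test_set list with `features` and `labels` as in
#'   [train_classifier()].
#' @param threshold probability cut for the positive call (default 0.5).
#' @return an `eval_result` list: `confusion`, `recall`, `precision`, `f1`,
#'   `accuracy`, `auc`, `roc_points`, `scores`.
#' @export
evaluate_classifier <- function(model, test_set, threshold = 0.5) {
  scores <- predict_classifier(model, test_set$features)
  y <- labels_to_binary(test_set$labels)
  cm <- confusion_matrix(as.numeric(scores > threshold), y)
  mets <- confusion_metrics(cm)
  roc <- roc_auc(scores, y)
  structure(
    c(list(confusion = cm), mets[c("recall", "precision", "f1", "accuracy")],
      list(auc = roc$auc, roc_points = roc$roc_points, scores = scores)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result>\n")
  cat(sprintf("  confusion: TP %d  FP %d  FN %d  TN %d\n",
              x$confusion["tp"], x$confusion["fp"],
              x$confusion["fn"], x$confusion["tn"]))
  cat(sprintf(
    "  recall %.3f  precision %.3f  F1 %.3f  accuracy %.3f  AUC %.3f\n",
    x$recall, x$precision, x$f1, x$accuracy, x$auc
  ))
  invisible(x)
}

#' Write an evaluation report as JSON (plus ROC points CSV)
#'
#' @param result an `eval_result`.
#' @param path JSON destination; the ROC points go to the same stem with
#'   suffix `_roc.csv`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(result, path) {
  jsonlite::write_json(
    list(
      confusion = as.list(result$confusion),
      recall = result$recall, precision = result$precision,
      f1 = result$f1, accuracy = result$accuracy, auc = result$auc
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  roc_path <- sub("\\.json$", "_roc.csv", path)
  write.csv(result$roc_points, roc_path, row.names = FALSE)
  invisible(path)
}
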