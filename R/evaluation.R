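#' Confusion matrix for binary arousal decisions
#'
#' Counts true/false positives and negatives, with "arousal" (1) as the
#' positive class.
#'
#' @param labels logical or 0/1 vector of ground-truth segment labels.
#' @param predictions logical or 0/1 vector of predicted labels.
#' @return An object of class `confusion_matrix`: a list with integer
#'   fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  if (length(labels) == 0L) stop("empty input")
  y <- as.integer(as.logical(labels))
  p <- as.integer(as.logical(predictions))
  if (anyNA(y) || anyNA(p)) stop("labels/predictions must be 0/1 without NA")
  cm <- list(
    tp = sum(y == 1L & p == 1L),
    tn = sum(y == 0L & p == 0L),
    fp = sum(y == 0L & p == 1L),
    fn = sum(y == 1L & p == 0L)
  )
  structure(cm, class = "confusion_matrix")
}

#' Accuracy, sensitivity, specificity and precision from a confusion matrix
#'
#' Accuracy = (TP+TN)/(TP+FP+FN+TN), sensitivity = TP/(TP+FN),
#' specificity = TN/(FP+TN), precision = TP/(TP+FP).  A metric whose
#' denominator is zero is undefined and reported as `NA` with a warning.
#'
#' @param cm a `confusion_matrix`.
#' @return A list with fields `accuracy`, `sensitivity`, `specificity`,
#'   `precision` (proportions in `[0, 1]`) and the counts.
#' @export
eval_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0L) stop("all-zero confusion matrix")
  ratio <- function(num, den, what) {
    if (den == 0L) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  list(
    accuracy    = (cm$tp + cm$tn) / total,
    sensitivity = ratio(cm$tp, cm$tp + cm$fn, "sensitivity"),
    specificity = ratio(cm$tn, cm$fp + cm$tn, "specificity"),
    precision   = ratio(cm$tp, cm$tp + cm$fp, "precision"),
    tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn
  )
}

#' Area under the ROC curve
#'
#' Computed with the rank (Mann-Whitney) statistic using midranks, so tied
#' scores count one half; this is exactly the probability that a random
#' positive outscores a random negative, and equals trapezoidal integration
#' of the ROC curve over all thresholds.
#'
#' @param labels 0/1 ground truth; both classes must be present.
#' @param scores numeric scores (higher = more arousal-like).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  y <- as.integer(as.logical(labels))
  if (length(y) != length(scores)) stop("labels and scores must match")
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' True-positive rate against false-positive rate at every distinct score
#' threshold, ordered from (0,0) to (1,1).
#'
#' @inheritParams auroc
#' @return A data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, scores) {
  y <- as.integer(as.logical(labels))
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  keep <- c(diff(ss) != 0, TRUE)  # last index of each tied block
  tpr <- cumsum(ys)[keep] / npos
  fpr <- cumsum(1 - ys)[keep] / nneg
  data.frame(threshold = c(Inf, ss[keep]),
             fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Record-disjoint k-fold cross-validation
#'
#' Records (not segments) are partitioned into `k` folds so that no
#' subject contributes to both the training and validation side of a fold,
#' avoiding within-record leakage.  `pipeline` is a function
#' `function(train_idx, test_idx)` returning a list with elements `labels`,
#' `predictions` and optionally `scores` for the held-out segments.
#'
#' @param record_ids vector assigning each segment to a source record.
#' @param k number of folds (default 5).
#' @param pipeline training/prediction callback (see Details).
#' @param seed integer seed for the fold shuffle.
#' @return A list with `folds` (per-fold metric lists) and `mean`
#'   (unweighted across-fold averages).
#' @export
crossval <- function(record_ids, k = 5, pipeline, seed = 1L) {
  ids <- unique(record_ids)
  if (k < 2) stop("k must be >= 2")
  if (length(ids) < k) stop("fewer records than folds")
  set.seed(seed)
  shuffled <- sample(ids)
  fold_of <- rep_len(seq_len(k), length(ids))[order(order(shuffled))]
  names(fold_of) <- shuffled
  fold_assign <- fold_of[match(record_ids, names(fold_of))]

  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_assign == f)
    train_idx <- which(fold_assign != f)
    res <- pipeline(train_idx, test_idx)
    m <- eval_metrics(confusion(res$labels, res$predictions))
    if (!is.null(res$scores) &&
        length(unique(as.integer(res$labels))) == 2L)
      m$auroc <- auroc(res$labels, res$scores)
    folds[[f]] <- m
  }
  metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                    if (!is.null(folds[[1]]$auroc)) "auroc")
  means <- sapply(metric_names, function(nm)
    mean(vapply(folds, function(x) x[[nm]], numeric(1)), na.rm = TRUE))
  list(folds = folds, mean = as.list(means))
}

#' Format an evaluation report the way clinical tables print it
#'
#' @param metrics list from [eval_metrics()] (optionally with `auroc`).
#' @return named character vector of percentages with two decimals.
#' @export
format_report <- function(metrics) {
  keys <- intersect(c("accuracy", "sensitivity", "specificity",
                      "precision", "auroc"), names(metrics))
  vapply(metrics[keys],
         function(v) sprintf("%.2f%%", 100 * v), character(1))
}
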