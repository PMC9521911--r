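#' One-vs-rest confusion counts
#'
#' Standard binary tallies after collapsing labels to positive vs rest.
#'
#' @param y_true,y_pred label vectors of equal, non-zero length.
#' @param positive_class the class treated as positive.
#' @return an object of class `confusion_counts`: list with `tp`, `tn`,
#'   `fp`, `fn` (their sum is the number of items).
#' @export
confusion_counts <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred)) {
    stop_param("y_true and y_pred must have equal length")
  }
  if (length(y_true) == 0L) stop_param("inputs must be non-empty")
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' F1 score from confusion counts, as a percent
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, reported as a percent rounded half away
#' from zero to one decimal — the convention used for detection F-scores in
#' the field's comparison tables.
#'
#' @param counts a [confusion_counts] object, or the TP count when `fp` and
#'   `fn` are given directly.
#' @param fp,fn false positive / false negative counts (when `counts` is a
#'   bare TP count).
#' @return percent in \[0, 100\], one decimal.
#' @export
f1_from_counts <- function(counts, fp = NULL, fn = NULL) {
  if (inherits(counts, "confusion_counts")) {
    tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  } else {
    tp <- counts
    if (is.null(fp) || is.null(fn)) stop_param("supply fp and fn with a bare TP")
  }
  den <- 2 * tp + fp + fn
  if (den <= 0) stop_param("undefined F1: 2*TP + FP + FN must be > 0")
  round_half_away(100 * 2 * tp / den, 1)
}

#' Multiclass accuracy, sensitivity, specificity
#'
#' Accuracy is the overall fraction correct. Sensitivity and specificity are
#' macro-averages of the per-class one-vs-rest recall and true-negative rate
#' (`average = "micro"` pools the per-class counts instead). All three are
#' reported as percents.
#'
#' @param y_true,y_pred label vectors over the same class set.
#' @param classes class labels; defaults to the union observed in `y_true`.
#' @param average `"macro"` (default) or `"micro"`.
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent).
#' @export
multiclass_metrics <- function(y_true, y_pred, classes = NULL,
                               average = c("macro", "micro")) {
  average <- match.arg(average)
  if (length(y_true) == 0L) stop_param("inputs must be non-empty")
  if (length(y_true) != length(y_pred)) {
    stop_param("y_true and y_pred must have equal length")
  }
  if (is.null(classes)) classes <- sort(unique(as.character(y_true)))
  cc <- lapply(classes, function(cl) confusion_counts(y_true, y_pred, cl))
  if (average == "macro") {
    sens <- mean(vapply(cc, function(c) c$tp / max(c$tp + c$fn, 1), numeric(1)))
    spec <- mean(vapply(cc, function(c) c$tn / max(c$tn + c$fp, 1), numeric(1)))
  } else {
    tp <- sum(vapply(cc, `[[`, numeric(1), "tp"))
    fn <- sum(vapply(cc, `[[`, numeric(1), "fn"))
    tn <- sum(vapply(cc, `[[`, numeric(1), "tn"))
    fp <- sum(vapply(cc, `[[`, numeric(1), "fp"))
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
  }
  list(accuracy = 100 * mean(y_true == y_pred),
       sensitivity = 100 * sens,
       specificity = 100 * spec)
}

# binary AUC via midranks (Mann-Whitney); labels logical/0-1, higher score
# means more positive
binary_auc <- function(is_pos, scores) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # midranks for ties
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest multiclass ROC AUC
#'
#' Macro averaging computes a binary rank-based AUC per class (that class
#' against the rest, scored by its softmax column, ties by midranks) and
#' averages them unweighted. Micro averaging pools all (indicator, score)
#' pairs across classes into one binary AUC.
#'
#' @param y_true labels drawn from `colnames(scores)` (or class indices).
#' @param scores n x K matrix of class scores (e.g. softmax probabilities),
#'   columns in class order.
#' @param average `"macro"` or `"micro"`.
#' @param classes class labels matching the score columns; defaults to
#'   `colnames(scores)`.
#' @return AUC in \[0, 1\].
#' @export
ovr_roc_auc <- function(y_true, scores, average = c("macro", "micro"),
                        classes = NULL) {
  average <- match.arg(average)
  scores <- as.matrix(scores)
  if (is.null(classes)) classes <- colnames(scores)
  if (is.null(classes)) stop_param("supply `classes` or name the score columns")
  if (length(y_true) != nrow(scores)) {
    stop_param("y_true length must match nrow(scores)")
  }
  y_true <- as.character(y_true)
  if (average == "macro") {
    aucs <- vapply(seq_along(classes), function(k) {
      binary_auc(y_true == classes[k], scores[, k])
    }, numeric(1))
    if (anyNA(aucs)) {
      missing <- classes[is.na(aucs)]
      stop_param("macro AUC undefined: class(es) absent from y_true: ",
                 paste(missing, collapse = ", "))
    }
    mean(aucs)
  } else {
    ind <- as.vector(vapply(seq_along(classes),
                            function(k) y_true == classes[k],
                            logical(length(y_true))))
    binary_auc(ind, as.vector(scores))
  }
}

#' Seeded k-fold split, optionally stratified
#'
#' Partitions `1:n` into `k` folds whose sizes differ by at most one. With
#' `labels` supplied, each class is dealt across folds separately, keeping
#' per-fold class proportions within one item of the global proportions.
#'
#' @param n number of items (`n >= k`).
#' @param k fold count (default 10).
#' @param seed integer seed.
#' @param labels optional label vector of length `n` for stratification.
#' @return list of `k` lists, each with `train` and `test` index vectors.
#' @export
kfold_split <- function(n, k = 10L, seed = NULL, labels = NULL) {
  n <- as_count(n, "n"); k <- as_count(k, "k")
  if (n < k) stop_param("n must be >= k")
  assign_folds <- function() {
    fold_of <- integer(n)
    if (is.null(labels)) {
      fold_of <- rep_len(seq_len(k), n)[sample.int(n)]
    } else {
      if (length(labels) != n) stop_param("labels must have length n")
      offset <- 0L
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold_of[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
        offset <- offset + length(idx)
      }
    }
    fold_of
  }
  fold_of <- if (is.null(seed)) assign_folds() else with_seed(seed, assign_folds())
  lapply(seq_len(k), function(j) {
    list(train = which(fold_of != j), test = which(fold_of == j))
  })
}
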