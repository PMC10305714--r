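#' Binary classification counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts (true/false
#'   positive/negative).
#' @return A list of class `metrics_counts`.
#' @export
metrics_counts <- function(tp = 0L, fp = 0L, tn = 0L, fn = 0L) {
  vals <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(vals < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(as.list(vals), class = "metrics_counts")
}

#' Accuracy from counts
#'
#' `100 * (tp + tn) / (tp + tn + fp + fn)`, in percent.
#'
#' @param counts A [metrics_counts()].
#' @return Accuracy in percent.
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("accuracy undefined for zero total count", call. = FALSE)
  100 * (counts$tp + counts$tn) / total
}

#' Precision, recall and F1 from counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f1 = 2PR / (P + R)`.  Zero denominators return 0 by convention.
#'
#' @param counts A [metrics_counts()].
#' @return Named numeric vector `(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(counts) {
  p <- safe_div(counts$tp, counts$tp + counts$fp)
  r <- safe_div(counts$tp, counts$tp + counts$fn)
  c(precision = p, recall = r, f1 = f1_score(p, r))
}

#' @rdname precision_recall_f1
#' @param precision,recall Scalars in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Confusion matrix
#'
#' @param y_true,y_pred Equal-length integer label vectors with codes in
#'   `0 .. n_classes - 1`.
#' @param n_classes Number of classes (default 16).
#' @return An `n_classes x n_classes` count matrix; entry `(i, j)` counts
#'   items of true class `i - 1` predicted as class `j - 1`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 16L) {
  if (length(y_true) != length(y_pred)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (length(y_true) &&
      (min(c(y_true, y_pred)) < 0 || max(c(y_true, y_pred)) >= n_classes)) {
    stop("labels outside 0..n_classes-1", call. = FALSE)
  }
  m <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    m[y_true[i] + 1L, y_pred[i] + 1L] <- m[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  dimnames(m) <- list(true = 0:(n_classes - 1L), pred = 0:(n_classes - 1L))
  m
}

# One-vs-rest counts for class `i` (1-based row/col) of a confusion matrix.
counts_from_confusion <- function(confusion, i) {
  tp <- confusion[i, i]
  fp <- sum(confusion[, i]) - tp
  fn <- sum(confusion[i, ]) - tp
  tn <- sum(confusion) - tp - fp - fn
  metrics_counts(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Per-class metric table from a confusion matrix
#'
#' @param confusion Square count matrix from [confusion_matrix()].
#' @return Data frame with one row per class: `code`, `precision`, `recall`,
#'   `f1`, `support`.
#' @export
per_class_metrics <- function(confusion) {
  n <- nrow(confusion)
  rows <- lapply(seq_len(n), function(i) {
    prf <- precision_recall_f1(counts_from_confusion(confusion, i))
    data.frame(code = i - 1L, precision = prf["precision"],
               recall = prf["recall"], f1 = prf["f1"],
               support = sum(confusion[i, ]), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Support-weighted average of per-class metrics
#'
#' @param values Per-class metric values.
#' @param supports Non-negative class supports with a positive sum.
#' @return The support-weighted arithmetic mean.
#' @export
weighted_average <- function(values, supports) {
  if (any(supports < 0) || sum(supports) == 0) {
    stop("supports must be non-negative with positive total", call. = FALSE)
  }
  sum(values * supports) / sum(supports)
}

#' Type-level (group) report
#'
#' Collapses the 16 activity classes to the four type groups (Crossroad,
#' Parking, Roundabout, Secondary) via the name prefixes, then scores each
#' group one-vs-rest on the collapsed 4x4 confusion: accuracy (percent),
#' precision, recall, F1.  Also collapses to primary vs secondary and
#' reports the binary accuracy in percent.
#'
#' @param confusion A 16x16 matrix from [confusion_matrix()].
#' @return List with `groups` (data frame: group, accuracy, precision,
#'   recall, f1, support) and `binary_primary_secondary_accuracy`.
#' @export
type_level_report <- function(confusion) {
  stopifnot(nrow(confusion) == 16L, ncol(confusion) == 16L)
  tab <- activity_labels()
  groups <- activity_groups()
  gidx <- match(tab$type_group, groups)
  g4 <- matrix(0, 4L, 4L, dimnames = list(true = groups, pred = groups))
  for (i in 1:16) for (j in 1:16) {
    g4[gidx[i], gidx[j]] <- g4[gidx[i], gidx[j]] + confusion[i, j]
  }
  rows <- lapply(seq_along(groups), function(i) {
    cnt <- counts_from_confusion(g4, i)
    prf <- precision_recall_f1(cnt)
    data.frame(group = groups[i], accuracy = accuracy(cnt),
               precision = prf["precision"], recall = prf["recall"],
               f1 = prf["f1"], support = sum(g4[i, ]), row.names = NULL)
  })
  primary <- tab$is_primary
  b2 <- matrix(0, 2L, 2L)
  for (i in 1:16) for (j in 1:16) {
    b2[2L - primary[i], 2L - primary[j]] <-
      b2[2L - primary[i], 2L - primary[j]] + confusion[i, j]
  }
  list(
    groups = do.call(rbind, rows),
    group_confusion = g4,
    binary_primary_secondary_accuracy = 100 * sum(diag(b2)) / sum(b2)
  )
}

#' Full evaluation report
#'
#' Confusion matrix, per-class precision/recall/F1 with supports,
#' support-weighted averages, overall accuracy, the type-level group report
#' and the binary primary/secondary accuracy.
#'
#' @param y_true,y_pred Integer label vectors (codes `0..15`).
#' @param n_classes Number of classes (default 16).
#' @return A list of class `evaluation_report`.
#' @export
evaluation_report <- function(y_true, y_pred, n_classes = 16L) {
  confusion <- confusion_matrix(y_true, y_pred, n_classes)
  per_class <- per_class_metrics(confusion)
  tab <- activity_labels()
  if (n_classes == 16L) per_class$name <- tab$name
  weighted <- c(
    precision = weighted_average(per_class$precision, per_class$support),
    recall = weighted_average(per_class$recall, per_class$support),
    f1 = weighted_average(per_class$f1, per_class$support)
  )
  type_level <- if (n_classes == 16L) type_level_report(confusion) else NULL
  structure(list(
    confusion = confusion,
    per_class = per_class,
    weighted = weighted,
    overall_accuracy = 100 * sum(diag(confusion)) / max(1, sum(confusion)),
    type_level = type_level$groups,
    group_confusion = type_level$group_confusion,
    binary_primary_secondary_accuracy =
      type_level$binary_primary_secondary_accuracy
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 2, ...) {
  cat(sprintf("Overall accuracy: %.1f%%\n", x$overall_accuracy))
  cat(sprintf("Weighted precision/recall/F1: %.2f / %.2f / %.2f\n",
              x$weighted["precision"], x$weighted["recall"], x$weighted["f1"]))
  cat("\nPer-class metrics:\n")
  pc <- x$per_class
  pc[c("precision", "recall", "f1")] <- round(pc[c("precision", "recall", "f1")],
                                              digits)
  print(pc, row.names = FALSE)
  if (!is.null(x$type_level)) {
    cat("\nType-level metrics:\n")
    tl <- x$type_level
    tl$accuracy <- round(tl$accuracy, 1)
    tl[c("precision", "recall", "f1")] <- round(tl[c("precision", "recall", "f1")],
                                                digits)
    print(tl, row.names = FALSE)
    cat(sprintf("\nBinary primary/secondary accuracy: %.1f%%\n",
                x$binary_primary_secondary_accuracy))
  }
  invisible(x)
}

#' Principal-component embedding
#'
#' Projects feature vectors onto the top principal components, for
#' visualising how well the classes separate in the learned feature space.
#'
#' @param x Numeric matrix (items in rows).
#' @param dims Number of components, 2 or 3.
#' @return Matrix of coordinates (`n x dims`) with attribute
#'   `explained_variance` (component variances, non-increasing).
#' @export
pca_embed <- function(x, dims = 2L) {
  x <- as.matrix(x)
  if (dims > ncol(x)) {
    stop("dims exceeds the feature dimension", call. = FALSE)
  }
  if (nrow(x) < dims) stop("need at least dims rows", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  coords <- pc$x[, seq_len(dims), drop = FALSE]
  attr(coords, "explained_variance") <- pc$sdev[seq_len(dims)]^2
  coords
}
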