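# Confusion-matrix construction, Matthews correlation (binary and the
# multiclass generalization), derived metrics, per-participant aggregation
# and between-condition rank-sum testing.

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the order of
#' `classes`.
#'
#' @param y_true,y_pred Label vectors of equal length; all labels must be
#'   in `classes`.
#' @param classes Ordered class labels; defaults to the sorted union of
#'   factor levels / observed labels.
#' @return A `confusion_matrix` (integer matrix with class attribute).
#' @export
confusion <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred))
    stopf("y_true (%d) and y_pred (%d) differ in length",
          length(y_true), length(y_pred))
  if (is.null(classes)) {
    classes <- if (is.factor(y_true)) levels(y_true)
               else sort(unique(c(as.character(y_true), as.character(y_pred))))
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  m <- table(factor(y_true, levels = classes),
             factor(y_pred, levels = classes))
  out <- matrix(as.integer(m), length(classes), length(classes),
                dimnames = list(true = classes, predicted = classes))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Matthews correlation coefficient
#'
#' For two classes this is the classical
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; for more than
#' two classes the generalized multiclass correlation over the full
#' confusion matrix, which reduces to the binary formula for 2x2 input.
#' Any zero denominator yields 0 (the chance-level convention).
#'
#' @param cm A `confusion_matrix` (or plain square count matrix).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  cm <- unclass(cm)
  storage.mode(cm) <- "double"
  s <- sum(cm)
  if (s == 0) return(0)
  c_ <- sum(diag(cm))
  t_ <- rowSums(cm)   # true-class totals
  p_ <- colSums(cm)   # predicted-class totals
  num <- c_ * s - sum(t_ * p_)
  den <- sqrt(s^2 - sum(p_^2)) * sqrt(s^2 - sum(t_^2))
  if (den == 0) return(0)
  num / den
}

#' Metric suite derived from a confusion matrix
#'
#' Accuracy plus F1, precision, recall and specificity.  With more than two
#' classes the latter four are computed one-vs-rest per class and
#' macro-averaged; with exactly two classes they refer to the positive
#' class (the second class, e.g. SLEEP in sleep--wake detection).  A class
#' absent from the truth contributes recall 0 by convention.
#'
#' @param cm A `confusion_matrix`.
#' @return Named list: `mcc`, `accuracy`, `f1`, `precision`, `recall`,
#'   `specificity`.
#' @export
metrics <- function(cm) {
  cmu <- unclass(cm); storage.mode(cmu) <- "double"
  s <- sum(cmu)
  k <- nrow(cmu)
  acc <- if (s > 0) sum(diag(cmu)) / s else 0
  per_class <- vapply(seq_len(k), function(i) {
    tp <- cmu[i, i]
    fn <- sum(cmu[i, -i]); fp <- sum(cmu[-i, i])
    tn <- s - tp - fn - fp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, spec, f1)
  }, numeric(4))
  pcs <- if (k == 2) per_class[, 2] else rowMeans(per_class)
  list(mcc = mcc(cm), accuracy = acc, f1 = pcs[4], precision = pcs[1],
       recall = pcs[2], specificity = pcs[3])
}

#' Per-participant metric table
#'
#' One metric row per participant plus median and IQR summaries across
#' participants (the usual boxplot summaries).
#'
#' @param y_true,y_pred Aligned label vectors.
#' @param ids Participant id per element.
#' @param classes Ordered class labels (defaults as in [confusion()]).
#' @return List with `table` (data frame, one row per participant) and
#'   `summary` (median and IQR of each metric).
#' @export
per_participant <- function(y_true, y_pred, ids, classes = NULL) {
  stopifnot(length(y_true) == length(y_pred),
            length(y_true) == length(ids))
  if (is.null(classes)) {
    classes <- if (is.factor(y_true)) levels(y_true)
               else sort(unique(as.character(y_true)))
  }
  rows <- lapply(split(seq_along(ids), ids), function(ix) {
    as.data.frame(metrics(confusion(y_true[ix], y_pred[ix], classes)))
  })
  tab <- cbind(participant_id = names(rows), do.call(rbind, rows))
  rownames(tab) <- NULL
  met <- c("mcc", "accuracy", "f1", "precision", "recall", "specificity")
  summ <- data.frame(
    metric = met,
    median = vapply(met, function(m) median(tab[[m]]), 0),
    iqr = vapply(met, function(m) quantile(tab[[m]], 0.75, names = FALSE) -
                                  quantile(tab[[m]], 0.25, names = FALSE), 0))
  rownames(summ) <- NULL
  list(table = tab, summary = summ)
}

#' Compare two conditions with a rank-sum test
#'
#' Two-sided Mann--Whitney U test with Bonferroni adjustment over an
#' explicit, caller-declared family of comparisons; stars at adjusted
#' p < .05 / .01 / .001.
#'
#' @param a,b Numeric metric samples (e.g. per-participant MCCs).
#' @param n_comparisons Bonferroni family size (default 1).
#' @return A `comparison_result`: `statistic` (U), `p_raw`, `p_adjusted`,
#'   `n_comparisons`, `stars`.
#' @export
compare_conditions <- function(a, b, n_comparisons = 1) {
  if (!length(a) || !length(b)) stopf("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1) {
    warning("all pooled values identical; p = 1 by convention",
            call. = FALSE)
    res <- list(statistic = length(a) * length(b) / 2, p_raw = 1)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    res <- list(statistic = unname(wt$statistic), p_raw = wt$p.value)
  }
  p_adj <- min(1, res$p_raw * n_comparisons)
  stars <- if (p_adj < 0.001) "***" else if (p_adj < 0.01) "**"
           else if (p_adj < 0.05) "*" else ""
  structure(list(statistic = res$statistic, p_raw = res$p_raw,
                 p_adjusted = p_adj, n_comparisons = n_comparisons,
                 stars = stars),
            class = "comparison_result")
}
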