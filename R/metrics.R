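#' Multiclass confusion matrix
#'
#' Counts of (true grade, predicted grade) pairs: rows are true labels,
#' columns predictions, both `0 .. K-1`.
#'
#' @param truth,estimate Integer vectors of equal length with values in
#'   `0 .. K-1`.
#' @param k Number of classes (default 5).
#' @return A `K x K` integer matrix with dimnames the grade labels.
#' @section Errors: `fundusdr_length_mismatch` when the vectors differ in
#'   length.
#' @export
confusion_matrix <- function(truth, estimate, k = 5L) {
  if (length(truth) != length(estimate))
    stop_fdr("length_mismatch", "truth and estimate differ in length")
  truth <- as.integer(truth); estimate <- as.integer(estimate)
  stopifnot(all(truth >= 0L & truth < k), all(estimate >= 0L & estimate < k))
  lv <- 0:(k - 1L)
  cm <- table(factor(truth, levels = lv), factor(estimate, levels = lv))
  m <- matrix(as.integer(cm), k, k, dimnames = list(true = lv, predicted = lv))
  m
}

# one-vs-rest counts per class from a confusion matrix
ovr_counts <- function(cm) {
  k <- nrow(cm); n <- sum(cm)
  tp <- unname(diag(cm))
  fp <- unname(colSums(cm)) - tp
  fn <- unname(rowSums(cm)) - tp
  tibble::tibble(grade = 0:(k - 1L), tp = tp, fp = fp, fn = fn,
                 tn = n - tp - fp - fn, support = unname(rowSums(cm)))
}

safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Per-class one-vs-rest scores
#'
#' Treating each grade in turn as positive: precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, specificity `TN/(FP+TN)`, and F1 the harmonic mean of
#' precision and recall. Ratios with zero denominators are reported as 0.
#'
#' @param cm A confusion matrix from [confusion_matrix()].
#' @return A tibble with one row per grade: `grade`, `tp`, `fp`, `fn`, `tn`,
#'   `support`, `precision`, `recall`, `specificity`, `f1`.
#' @export
per_class_scores <- function(cm) {
  counts <- ovr_counts(cm)
  dplyr::mutate(counts,
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    specificity = safe_div(tn, fp + tn),
    f1 = safe_div(2 * precision * recall, precision + recall)
  )
}

#' Aggregate multiclass scores
#'
#' Accuracy is the diagonal fraction of the confusion matrix. ACA (average
#' classification accuracy) row-normalizes the matrix and averages the
#' diagonal, i.e. the mean per-class recall. Macro-F1 is the unweighted
#' mean of per-class F1; micro-F1 pools one-vs-rest counts globally,
#' `TP / (TP + (FP + FN) / 2)`, which for single-label multiclass equals
#' accuracy.
#'
#' @inheritParams per_class_scores
#' @return A one-row tibble: `accuracy`, `aca`, `macro_f1`, `micro_f1`.
#' @section Errors: `fundusdr_empty_class` for ACA when some true grade has
#'   no samples (a zero row).
#' @export
aggregate_scores <- function(cm) {
  if (any(rowSums(cm) == 0))
    stop_fdr("empty_class",
             "ACA is undefined when a true grade has no samples")
  pc <- per_class_scores(cm)
  tibble::tibble(
    accuracy = sum(diag(cm)) / sum(cm),
    aca = mean(diag(cm / rowSums(cm))),
    macro_f1 = mean(pc$f1),
    micro_f1 = sum(pc$tp) / (sum(pc$tp) + (sum(pc$fp) + sum(pc$fn)) / 2)
  )
}

#' One-vs-rest ranking AUC, macro-averaged
#'
#' For each grade, the probability column for that grade is used to rank
#' samples; the AUC is the Mann-Whitney statistic (midranks for ties)
#' between that grade's samples and the rest. The macro average over grades
#' is returned.
#'
#' @param truth Integer vector of true grades `0 .. K-1`.
#' @param prob A samples x classes matrix of predicted probabilities (rows
#'   sum to 1).
#' @return A single number in `[0, 1]`.
#' @section Errors: `fundusdr_degenerate_class` when some grade has no
#'   positive or no negative samples.
#' @export
auc_ovr <- function(truth, prob) {
  stopifnot(is.matrix(prob), nrow(prob) == length(truth))
  k <- ncol(prob)
  aucs <- vapply(seq_len(k), function(j) {
    pos <- as.integer(truth) == (j - 1L)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L)
      stop_fdr("degenerate_class", sprintf(
        "grade %d has no %s samples; its one-vs-rest AUC is undefined",
        j - 1L, if (n1 == 0L) "positive" else "negative"))
    r <- rank(prob[, j], ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  mean(aucs)
}

#' Full evaluation report
#'
#' Bundles the confusion matrix, per-class scores, aggregate scores and
#' (when probabilities are supplied) the macro one-vs-rest AUC into a
#' single object with [tidy()], [glance()] and [autoplot()] methods.
#'
#' @inheritParams confusion_matrix
#' @param prob Optional samples x classes probability matrix for AUC.
#' @return An object of class `dr_metrics`: a list with `confusion`,
#'   `per_class` (tibble), `aggregate` (one-row tibble, including `auc` when
#'   available).
#' @export
metrics_report <- function(truth, estimate, prob = NULL, k = 5L) {
  cm <- confusion_matrix(truth, estimate, k)
  agg <- aggregate_scores(cm)
  agg$auc <- if (is.null(prob)) NA_real_ else auc_ovr(truth, prob)
  structure(list(confusion = cm, per_class = per_class_scores(cm),
                 aggregate = agg),
            class = "dr_metrics")
}

#' @exportS3Method generics::tidy
tidy.dr_metrics <- function(x, ...) x$per_class

#' @exportS3Method generics::glance
glance.dr_metrics <- function(x, ...) x$aggregate

#' @export
print.dr_metrics <- function(x, digits = 2, ...) {
  cat("Five-grade classification report\n\nConfusion matrix (rows = true):\n")
  print(x$confusion)
  cat("\nPer-class scores:\n")
  print(as.data.frame(lapply(x$per_class, function(col)
    if (is.double(col)) round(col, digits) else col)), row.names = FALSE)
  cat("\nAggregate:\n")
  print(round(as.data.frame(x$aggregate), digits), row.names = FALSE)
  invisible(x)
}

#' Write a per-class report table
#'
#' Writes a CSV in the conventional per-class layout (one row per grade
#' with precision, recall, F1, specificity, accuracy and support, plus an
#' overall row). The per-class "accuracy" row follows the field's common
#' report convention of repeating recall (correct fraction within that true
#' grade); the overall row carries the global aggregate scores.
#'
#' @param report A [metrics_report()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "dr_metrics"))
  pc <- report$per_class
  per <- tibble::tibble(
    label = as.character(pc$grade),
    precision = pc$precision, recall = pc$recall, f1 = pc$f1,
    specificity = pc$specificity,
    accuracy = pc$recall,   # per-class accuracy == recall in this layout
    support = pc$support)
  agg <- report$aggregate
  overall <- tibble::tibble(
    label = "overall", precision = NA_real_, recall = NA_real_,
    f1 = agg$macro_f1, specificity = NA_real_, accuracy = agg$accuracy,
    support = sum(pc$support))
  readr::write_csv(dplyr::bind_rows(per, overall), path)
  invisible(path)
}
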