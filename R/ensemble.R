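#' F1-weighted voting weights with difference amplification
#'
#' Each base classifier i with validation score `F1[i]` receives the fusion
#' weight
#' \deqn{\lambda_i = F1_i / \sum_p F1_p + (F1_i - \overline{F1}) \cdot n}
#' the share of the total F1 plus the deviation from the mean amplified by
#' `n`. The deviations sum to zero, so the lambdas always sum to exactly 1;
#' `n` widens the gap between stronger and weaker classifiers without
#' changing the total. For large `n` a below-average classifier's lambda
#' can go negative; the formula is applied verbatim and a warning is
#' emitted (fused rows may then leave `[0, 1]`, though the argmax
#' prediction remains defined).
#'
#' @param f1_list Numeric vector of per-classifier validation F1 scores in
#'   `[0, 1]`.
#' @param n Amplification parameter, a real `>= 0` (0 reduces to pure
#'   F1-share weighting).
#' @return A tibble of class `ensemble_weights` with columns `classifier`,
#'   `f1`, `lambda`; `n` is stored as an attribute.
#' @section Errors: `fundusdr_all_zero_f1` when every F1 is 0.
#' @examples
#' compute_lambdas(c(0.87, 0.88, 0.88, 0.87, 0.87), n = 3)
#' @export
compute_lambdas <- function(f1_list, n) {
  stopifnot(length(f1_list) >= 1L, all(f1_list >= 0), all(f1_list <= 1),
            length(n) == 1L, n >= 0)
  total <- sum(f1_list)
  if (total == 0)
    stop_fdr("all_zero_f1", "every classifier has F1 = 0; weights undefined")
  lambda <- f1_list / total + (f1_list - mean(f1_list)) * n
  if (any(lambda < 0))
    rlang::warn(
      "some lambda weights are negative (n is large relative to the F1 spread); fused probability rows may leave [0, 1]",
      class = "fundusdr_negative_lambda")
  out <- tibble::tibble(classifier = seq_along(f1_list), f1 = f1_list,
                        lambda = lambda)
  structure(out, class = c("ensemble_weights", class(out)), n = n)
}

#' @exportS3Method generics::tidy
tidy.ensemble_weights <- function(x, ...) tibble::as_tibble(unclass(x))

#' Fuse per-classifier probability matrices by weighted soft voting
#'
#' The fused probability matrix is the lambda-weighted sum of the base
#' classifiers' samples x classes probability matrices; each sample's
#' predicted grade is the column of the maximum fused probability, with
#' ties broken toward the lowest grade.
#'
#' @param prob_matrices A list of samples x classes probability matrices,
#'   one per classifier, all the same shape.
#' @param weights An [compute_lambdas()] result (or a bare numeric vector
#'   of lambdas of matching length).
#' @return A list of class `fused_prediction` with elements `prob` (fused
#'   matrix) and `grade` (integer vector of predicted grades `0 .. K-1`).
#' @section Errors: `fundusdr_shape_mismatch` when matrix shapes or the
#'   weight count disagree.
#' @export
fuse_probabilities <- function(prob_matrices, weights) {
  lambda <- if (inherits(weights, "ensemble_weights")) weights$lambda
            else as.numeric(weights)
  stopifnot(is.list(prob_matrices), length(prob_matrices) >= 1L)
  dims <- unique(lapply(prob_matrices, dim))
  if (length(dims) != 1L || length(prob_matrices) != length(lambda))
    stop_fdr("shape_mismatch",
             "probability matrices must share one shape and match the number of weights")
  fused <- Reduce(`+`, purrr::map2(prob_matrices, lambda, `*`))
  grade <- max.col(fused, ties.method = "first") - 1L
  structure(list(prob = fused, grade = grade), class = "fused_prediction")
}

# score one n on a validation block; macro-F1 averages over the grades
# actually present so a small validation set missing a grade still scores
score_n <- function(n, f1_list, prob_matrices, truth, k) {
  w <- suppressWarnings(compute_lambdas(f1_list, n))
  fused <- fuse_probabilities(prob_matrices, w)
  cm <- confusion_matrix(truth, fused$grade, k)
  pc <- per_class_scores(cm)
  tibble::tibble(n = n,
                 accuracy = sum(diag(cm)) / sum(cm),
                 macro_f1 = mean(pc$f1[pc$support > 0]))
}

#' Two-stage grid search for the amplification parameter n
#'
#' Evaluates the ensemble on a coarse grid (by default 10, 20, ..., 100)
#' and then on a fine grid (1, 2, ..., 10), scoring each candidate's fused
#' predictions against `truth`. Returns the n maximizing macro-F1, with
#' accuracy and then the smaller n as tie-breakers. Score the validation
#' set here, not the test set, to avoid leaking the final evaluation.
#'
#' @inheritParams fuse_probabilities
#' @param f1_list Per-classifier validation F1 scores.
#' @param truth True grades aligned with the probability matrix rows.
#' @param coarse,fine Numeric grids for the two stages.
#' @param k Number of classes (default `ncol` of the matrices).
#' @return A list of class `n_search` with elements `n` (chosen value),
#'   `weights` (the [compute_lambdas()] result at that n) and `table`, a
#'   tibble (`stage`, `n`, `accuracy`, `macro_f1`) over both grids.
#' @export
select_n <- function(f1_list, prob_matrices, truth,
                     coarse = seq(10, 100, by = 10), fine = 1:10,
                     k = NULL) {
  k <- k %||% ncol(prob_matrices[[1]])
  stopifnot(nrow(prob_matrices[[1]]) == length(truth))
  tab <- dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(purrr::map(
      coarse, score_n, f1_list, prob_matrices, truth, k)), stage = "coarse"),
    dplyr::mutate(dplyr::bind_rows(purrr::map(
      fine, score_n, f1_list, prob_matrices, truth, k)), stage = "fine")
  )[, c("stage", "n", "accuracy", "macro_f1")]
  best <- tab[order(-tab$macro_f1, -tab$accuracy, tab$n), ][1, ]
  structure(list(
    n = best$n,
    weights = suppressWarnings(compute_lambdas(f1_list, best$n)),
    table = tab
  ), class = "n_search")
}

#' @exportS3Method generics::tidy
tidy.n_search <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.n_search <- function(x, ...) {
  best <- x$table[x$table$n == x$n, ][1, ]
  tibble::tibble(n = x$n, accuracy = best$accuracy, macro_f1 = best$macro_f1)
}

#' @export
print.n_search <- function(x, ...) {
  cat("Amplification parameter search (two-stage grid)\n")
  cat("Chosen n =", x$n, "\n")
  print(glance(x))
  invisible(x)
}
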