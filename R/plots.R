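# ggplot2 autoplot methods for the result types

#' @exportS3Method ggplot2::autoplot
autoplot.balance_plan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(unclass(object))[, c("class", "count", "total")],
    c("count", "total"), names_to = "stage", values_to = "images")
  long$stage <- factor(long$stage, levels = c("count", "total"),
                       labels = c("original", "after upsampling"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$class),
                                     y = .data$images,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "class", y = "images", fill = NULL,
                  title = "Upsampling plan") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.n_search <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table, c("accuracy", "macro_f1"),
                              names_to = "metric", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$score,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$stage), scales = "free_x") +
    ggplot2::labs(title = "Amplification parameter search",
                  x = "n", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.dr_metrics <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::as_tibble(as.data.frame(cm))
  names(df) <- c("true", "predicted", "count")
  df <- dplyr::group_by(df, .data$true)
  df <- dplyr::mutate(df, frac = .data$count / sum(.data$count))
  df <- dplyr::ungroup(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$frac)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = "Confusion matrix (row-normalized shading)",
                  fill = "row frac") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
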