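#' Pipeline run configuration
#'
#' Declares every stage input of an end-to-end run: where the raw images
#' and manifest live (or how to synthesize them), preprocessing settings,
#' the split seed, the base classifier panel, the training schedule, the
#' amplification-parameter grids and the selection metric.
#'
#' @param data_dir Directory of raw images, or `NULL` to synthesize.
#' @param manifest Manifest CSV path (required when `data_dir` is given).
#' @param synth_counts Per-grade image counts for synthetic data (used when
#'   `data_dir` is `NULL`).
#' @param synth_side Canvas side for synthetic images.
#' @param preprocess A [preprocess_config()].
#' @param classifiers A list of [classifier_spec()] objects (the base
#'   classifier panel).
#' @param train A [train_config()].
#' @param use_class_weights Whether to weight the training loss by
#'   inverse-frequency [class_weights()].
#' @param coarse,fine Grids for [select_n()].
#' @param seed Master seed for the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(data_dir = NULL, manifest = NULL,
                       synth_counts = c(52, 8, 12, 5, 5), synth_side = 32L,
                       preprocess = preprocess_config(target_side = 32L),
                       classifiers = list(
                         classifier_spec("tiny_test", input_side = 32L),
                         classifier_spec("tiny_test", input_side = 32L),
                         classifier_spec("tiny_test", input_side = 32L,
                                         attention = "none")),
                       train = train_config(phase1_epochs = 15L,
                                            phase2_epochs = 5L,
                                            lr_phase1 = 0.05,
                                            lr_phase2 = 0.005),
                       use_class_weights = TRUE,
                       coarse = seq(10, 100, by = 10), fine = 1:10,
                       seed = 1L) {
  if (!is.null(data_dir) && is.null(manifest))
    stop_fdr("bad_config", "a manifest path is required with data_dir")
  sides <- unique(purrr::map_int(classifiers, "input_side"))
  if (length(sides) != 1L || sides != preprocess$target_side)
    stop_fdr("bad_config",
             "all classifier input sides must equal the preprocessing target side")
  structure(list(data_dir = data_dir, manifest = manifest,
                 synth_counts = synth_counts, synth_side = synth_side,
                 preprocess = preprocess, classifiers = classifiers,
                 train = train, use_class_weights = use_class_weights,
                 coarse = coarse, fine = fine, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the [run_config()]
#'   arguments, with `preprocess`, `train` and `classifiers` as nested
#'   maps.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pp <- do.call(preprocess_config, y$preprocess %||% list())
  tr <- do.call(train_config, y$train %||% list())
  cls <- if (is.null(y$classifiers)) NULL else
    purrr::map(y$classifiers, ~ do.call(classifier_spec, .x))
  args <- y[setdiff(names(y), c("preprocess", "train", "classifiers"))]
  args$preprocess <- pp
  args$train <- tr
  if (!is.null(cls)) args$classifiers <- cls
  do.call(run_config, args)
}

load_images <- function(paths) purrr::map(paths, read_fundus)

#' Run the full detection pipeline
#'
#' Orchestrates every stage: (optionally) synthesize a labelled image set,
#' preprocess, split 3:1:1, upsample the training minority classes to the
#' balance plan, train each base classifier with the two-phase schedule,
#' collect validation macro-F1 scores and test probability matrices, select
#' the amplification parameter n on the validation set, fuse the test
#' probabilities by weighted soft voting, and write the evaluation report.
#' Each stage's outputs land under `out_dir` so partial runs are
#' inspectable.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created; default a tempdir subdirectory).
#' @return A list of class `dr_run`: `dir`, `split`, `plan`,
#'   `classifiers` (trained panel), `f1_list`, `n_search`, `weights`,
#'   `fused` (test-set [fuse_probabilities()] result), `metrics`
#'   (test-set [metrics_report()]), `base_accuracy` (per-classifier test
#'   accuracy).
#' @export
run_pipeline <- function(config = run_config(),
                         out_dir = tempfile("dr_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  k <- config$classifiers[[1]]$n_classes

  # stage 1: data
  ds <- if (is.null(config$data_dir)) {
    make_labelled_set(config$synth_counts, file.path(out_dir, "raw"),
                      fundus_params(side = config$synth_side),
                      seed = config$seed)
  } else {
    m <- read_manifest(config$manifest)
    m$image <- file.path(config$data_dir, m$image)
    m
  }

  # stage 2: preprocess
  pp <- preprocess_dir(ds, file.path(out_dir, "processed"),
                       config$preprocess)
  proc <- tibble::tibble(image = pp$output_path, label = ds$label)

  # stage 3: split
  split <- split_311(proc, seed = config$seed)
  write_split(split, file.path(out_dir, "split"))
  train_df <- split[split$set == "train", ]
  valid_df <- split[split$set == "valid", ]
  test_df <- split[split$set == "test", ]

  # stage 4: balance the training set
  counts <- vapply(0:(k - 1L), function(g) sum(train_df$label == g),
                   integer(1))
  plan <- balance_plan(max(counts), pmax(counts[-which.max(counts)], 1L))
  maj <- which.max(counts) - 1L
  train_images <- load_images(train_df$image)
  train_labels <- train_df$label
  aug_images <- list(); aug_labels <- integer(0)
  minority <- setdiff(0:(k - 1L), maj)
  for (j in seq_along(minority)) {
    g <- minority[j]
    idx <- which(train_labels == g)
    if (!length(idx)) next
    up <- upsample_class(train_images[idx], plan$add_per_image[j],
                         seed = config$seed + g)
    aug_images <- c(aug_images, up$images)
    aug_labels <- c(aug_labels, rep(g, length(up$images)))
  }
  idx0 <- which(train_labels == maj)
  all_train <- c(train_images[idx0], aug_images)
  all_labels <- c(train_labels[idx0], aug_labels)

  # stage 5: train the panel
  tr <- config$train
  if (config$use_class_weights)
    tr$class_weights <- class_weights(all_labels, k)
  valid_images <- load_images(valid_df$image)
  test_images <- load_images(test_df$image)
  classifiers <- purrr::imap(config$classifiers, function(sp, i) {
    clf <- build_classifier(sp, seed = config$seed + 10L * i)
    clf <- train_two_phase(clf, all_train, all_labels,
                           valid_images, valid_df$label, tr)
    save_classifier(clf, file.path(out_dir, sprintf("model_%02d", i)))
    clf
  })
  f1_list <- purrr::map_dbl(classifiers, "validation_f1")

  # stage 6: probabilities, n search (validation), fusion (test)
  valid_probs <- purrr::map(classifiers, predict_proba, valid_images)
  test_probs <- purrr::map(classifiers, predict_proba, test_images)
  purrr::iwalk(test_probs, function(p, i) readr::write_csv(
    as.data.frame(p), file.path(out_dir, sprintf("test_probs_%02d.csv", i)),
    col_names = FALSE))
  search <- select_n(f1_list, valid_probs, valid_df$label,
                     coarse = config$coarse, fine = config$fine, k = k)
  readr::write_csv(search$table, file.path(out_dir, "n_search.csv"))
  readr::write_csv(tidy(search$weights), file.path(out_dir, "lambdas.csv"))
  fused <- fuse_probabilities(test_probs, search$weights)

  # stage 7: report
  metrics <- metrics_report(test_df$label, fused$grade, fused$prob, k)
  write_report(metrics, file.path(out_dir, "report.csv"))
  base_acc <- purrr::map_dbl(test_probs, function(p)
    mean(max.col(p, ties.method = "first") - 1L == test_df$label))

  structure(list(dir = out_dir, split = split, plan = plan,
                 classifiers = classifiers, f1_list = f1_list,
                 n_search = search, weights = search$weights, fused = fused,
                 metrics = metrics, base_accuracy = base_acc,
                 truth = test_df$label),
            class = "dr_run")
}

#' @export
print.dr_run <- function(x, ...) {
  cat("Five-grade DR pipeline run\n")
  cat("  run dir:   ", x$dir, "\n")
  cat("  panel:     ", length(x$classifiers), "base classifiers\n")
  cat("  val F1:    ", paste(sprintf("%.3f", x$f1_list), collapse = ", "),
      "\n")
  cat("  chosen n:  ", x$n_search$n, "\n")
  cat("  ensemble test accuracy:",
      sprintf("%.3f", x$metrics$aggregate$accuracy),
      " (best single:", sprintf("%.3f", max(x$base_accuracy)), ")\n")
  invisible(x)
}
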